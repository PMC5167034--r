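#' Inference parameter vector
#'
#' The parameters of the reduced introduction model as used for
#' inference: invader growth rate `r`, carrying capacity `K`, maximum
#' population size `N`, resident carrying capacity `K_R` (held fixed in
#' all scenarios) and the interaction strength `alpha`. Positive
#' parameters are sampled on the log scale; this constructor takes them
#' on the natural scale and derives the rates that the likelihood needs:
#' \deqn{\lambda = r N / K, \quad \mu = \lambda - r, \quad
#'       \bar\lambda = \lambda (1 - \alpha K_R / N), \quad
#'       \bar r = \bar\lambda - \mu, \quad \bar K = \bar r N / \bar\lambda.}
#' The death rate is recovered from the defining identities
#' (equivalently \eqn{\mu = \bar\lambda (N - \bar K)/N}), which is the
#' unique value consistent with \eqn{\bar r = \bar\lambda - \mu} and
#' \eqn{\bar K = \bar r N/\bar\lambda}.
#'
#' @param r Invader growth rate (day^-1), > 0.
#' @param K Invader carrying capacity (individuals), > 0.
#' @param N Invader maximum population size (individuals), > 0; `N >= K`
#'   is required so that the derived death rate is nonnegative.
#' @param K_R Resident carrying capacity (individuals), > 0.
#' @param alpha Interaction strength, >= 0.
#'
#' @return An object of class `"inference_params"` with the supplied
#'   values plus derived `lambda`, `mu`, `lambda_bar`, `r_bar`, `K_bar`.
#' @export
#' @examples
#' inference_params(r = 1, K = 10000, N = 15000, K_R = 10000, alpha = 0.5)
inference_params <- function(r, K, N, K_R, alpha) {
  stopifnot(r > 0, K > 0, N > 0, K_R > 0, alpha >= 0)
  if (N < K) stop("`N` must be >= `K` (otherwise the death rate is negative)")
  der <- derive_rates(r, K, N, K_R, alpha)
  structure(c(list(r = r, K = K, N = N, K_R = K_R, alpha = alpha), der),
            class = "inference_params")
}

# Rate derivation without validation; used in the MCMC hot path.
derive_rates <- function(r, K, N, K_R, alpha) {
  lambda <- r * N / K
  mu <- lambda - r
  lambda_bar <- lambda * (1 - alpha * K_R / N)
  if (lambda_bar < 0) lambda_bar <- 0
  r_bar <- lambda_bar - mu
  K_bar <- if (lambda_bar > 0) r_bar * N / lambda_bar else NaN
  list(lambda = lambda, mu = mu, lambda_bar = lambda_bar,
       r_bar = r_bar, K_bar = K_bar)
}

# Variance of the Gaussian transition density is floored at a quarter
# individual^2 so the density stays proper for vanishing dt or n_from.
.var_floor <- 0.25

# Mean and variance of the diffusion-approximation transition density for
# the reduced birth-death process, conditional on n_from, over an interval
# dt. Vectorised over n_from and dt; lambda_bar, mu, N are scalars.
#
# Mean: logistic solution written with the crowding coefficient
# lambda_bar/N so the r_bar -> 0 limit is exact. Variance:
#   sigma^2(t) = M_t^2 int_0^t H(n(s)) M_s^{-2} ds,
#   M_s = exp(int_0^s F'(n(u)) du),  F = B - D,  H = B + D,
# which for the logistic mean path integrates in closed form after the
# substitution u = exp(r_bar s) (the integrand becomes polynomial in u
# over u^2). Near r_bar = 0 the substitution degenerates and a composite
# Simpson quadrature on the stable s-parameterisation is used instead.
bdp_moments <- function(n_from, dt, lambda_bar, mu, N,
                        method = "analytic", nodes = 201L, tol = 1e-8) {
  if (length(lambda_bar) != 1L || length(mu) != 1L || length(N) != 1L) {
    stop("rate parameters must be scalars")
  }
  if (method != "analytic" && method != "quadrature") {
    stop("unknown method: ", method)
  }
  r_bar <- lambda_bar - mu
  b <- lambda_bar / N                     # crowding coefficient r_bar/K_bar
  m <- length(n_from)
  if (length(dt) != m) dt <- rep_len(dt, m)

  # --- mean ---
  x <- r_bar * dt
  # expm1(x)/r_bar is cancellation-free for any x; only r_bar = 0 needs
  # its limit
  phi <- if (r_bar == 0) dt else expm1(x) / r_bar
  h_end <- 1 + n_from * b * phi           # = (K+n0(e^{rt}-1))/K in K-form
  mean_t <- n_from * exp(x) / h_end

  if (any(x > 50)) {                      # far outside any sane regime
    mean_t[x > 50] <- NA_real_
  }

  # --- variance ---
  # the closed form cancels catastrophically as r_bar -> 0; quadrature
  # takes over below |r_bar * dt| = 1e-3 (closed-form error < 1e-10 above)
  if (method == "analytic" && all(abs(x) >= 1e-3)) {
    # fast path: all intervals take the closed form
    U <- exp(x)
    rho <- n_from * b / r_bar             # n0 lambda_bar / (r_bar N)
    abar <- 1 - rho
    hU <- abar + rho * U
    Mt <- U / hU^2
    I3 <- abar^3 * (1 - 1 / U) + 3 * abar^2 * rho * x +
      3 * abar * rho^2 * (U - 1) + rho^3 * (U^2 - 1) / 2
    I2 <- abar^2 * x + 2 * abar * rho * (U - 1) + rho^2 * (U^2 - 1) / 2
    var_t <- Mt^2 / r_bar *
      ((lambda_bar + mu) * n_from * I3 - b * n_from^2 * I2)
    var_t[!is.finite(mean_t)] <- NA_real_
    return(list(mean = mean_t, var = var_t))
  }
  var_t <- numeric(m)
  use_q <- (method == "quadrature") | abs(x) < 1e-3
  if (any(!use_q)) {
    i <- which(!use_q)
    U <- exp(x[i])
    rho <- n_from[i] * b / r_bar
    abar <- 1 - rho
    hU <- abar + rho * U
    Mt <- U / hU^2
    I3 <- abar^3 * (1 - 1 / U) + 3 * abar^2 * rho * x[i] +
      3 * abar * rho^2 * (U - 1) + rho^3 * (U^2 - 1) / 2
    I2 <- abar^2 * x[i] + 2 * abar * rho * (U - 1) + rho^2 * (U^2 - 1) / 2
    var_t[i] <- Mt^2 / r_bar *
      ((lambda_bar + mu) * n_from[i] * I3 - b * n_from[i]^2 * I2)
  }
  if (any(use_q)) {
    for (i in which(use_q)) {
      var_t[i] <- .bdp_var_quad(n_from[i], dt[i], lambda_bar, mu, N,
                                nodes = nodes, tol = tol)
    }
  }
  var_t[!is.finite(mean_t)] <- NA_real_
  list(mean = mean_t, var = var_t)
}

# Composite Simpson evaluation of the variance integral on the stable
# s-parameterisation; interval count is doubled until the relative change
# drops below tol (Richardson-style self check).
.bdp_var_quad <- function(n0, dt, lambda_bar, mu, N, nodes = 201L,
                          tol = 1e-8, max_doublings = 6L) {
  r_bar <- lambda_bar - mu
  b <- lambda_bar / N
  f_at <- function(s) {
    phi <- if (abs(r_bar) > 1e-12) expm1(r_bar * s) / r_bar else s
    hs <- 1 + n0 * b * phi
    ns <- n0 * exp(r_bar * s) / hs
    Ms <- exp(r_bar * s) / hs^2
    H <- (lambda_bar + mu) * ns - b * ns^2
    H / Ms^2
  }
  phiT <- if (abs(r_bar) > 1e-12) expm1(r_bar * dt) / r_bar else dt
  Mt <- exp(r_bar * dt) / (1 + n0 * b * phiT)^2
  simpson <- function(nn) {
    if (nn %% 2L == 0L) nn <- nn + 1L
    s <- seq(0, dt, length.out = nn)
    w <- rep(c(4, 2), length.out = nn - 2L)
    h <- s[2] - s[1]
    vals <- f_at(s)
    (h / 3) * (vals[1] + vals[nn] + sum(w * vals[2:(nn - 1L)]))
  }
  est <- simpson(nodes)
  nn <- nodes
  for (k in seq_len(max_doublings)) {
    nn <- 2L * (nn - 1L) + 1L
    est2 <- simpson(nn)
    if (abs(est2 - est) <= tol * max(abs(est2), .Machine$double.eps)) {
      est <- est2
      break
    }
    est <- est2
  }
  Mt^2 * est
}

#' Transition moments of the diffusion approximation
#'
#' Mean and variance of the Gaussian transition density for the invader
#' abundance after an interval `dt`, starting from `n_from`, under the
#' reduced (competition-absorbed) birth-death process. The mean is the
#' logistic solution with the effective growth rate and carrying
#' capacity; the variance follows from the diffusion (moment)
#' approximation \eqn{\sigma^2(t) = M_t^2 \int_0^t H(n(s)) M_s^{-2} ds}
#' with drift \eqn{F = B - D}, flux \eqn{H = B + D} and propagator
#' \eqn{M_t = \exp\int_0^t F'(n(s)) ds}. For the logistic mean path the
#' integral has a closed form, used by default; `method = "quadrature"`
#' evaluates it by adaptive composite Simpson instead (relative tolerance
#' `tol`), which is also the fallback wherever \eqn{\bar r \approx 0}
#' makes the closed form degenerate.
#'
#' @param n_from Starting abundance(s), > 0. Vectorised.
#' @param dt Interval length(s) (days), > 0.
#' @param theta An [inference_params()] object.
#' @param method `"analytic"` (closed form) or `"quadrature"`.
#' @param nodes Initial Simpson node count (quadrature path).
#' @param tol Relative tolerance for the quadrature self check.
#'
#' @return A list of class `"transition_moments"` with vectors `mean` and
#'   `var` and scalars `lambda_bar`, `mu`, `r_bar`, `K_bar`, `N`.
#' @export
#' @examples
#' th <- inference_params(r = 1, K = 10000, N = 15000, K_R = 10000,
#'                        alpha = 0.5)
#' transition_moments(40, 0.5, th)
transition_moments <- function(n_from, dt, theta,
                               method = c("analytic", "quadrature"),
                               nodes = 201L, tol = 1e-8) {
  stopifnot(inherits(theta, "inference_params"),
            is.numeric(n_from), all(n_from > 0),
            is.numeric(dt), all(dt > 0))
  mv <- bdp_moments(n_from, dt, theta$lambda_bar, theta$mu, theta$N,
                    method = match.arg(method), nodes = nodes, tol = tol)
  structure(
    list(mean = mv$mean, var = mv$var, lambda_bar = theta$lambda_bar,
         mu = theta$mu, r_bar = theta$r_bar, K_bar = theta$K_bar,
         N = theta$N),
    class = "transition_moments"
  )
}

#' Gaussian log-density of the transition
#'
#' Normal log-density with the transition mean and variance; the variance
#' is floored at 0.25 individuals^2 (a numerical guard far below any
#' demographic scale) so the density stays proper at tiny `dt`.
#'
#' @param x Abundance value(s) at which to evaluate.
#' @param moments A [transition_moments()] object (or list with `mean`,
#'   `var`).
#' @return Log-density value(s).
#' @export
gaussian_logdensity <- function(x, moments) {
  if (any(!is.finite(x)) || any(!is.finite(moments$mean)) ||
      any(!is.finite(moments$var))) {
    stop("non-finite inputs to gaussian_logdensity")
  }
  dnorm(x, mean = moments$mean, sd = sqrt(pmax(moments$var, .var_floor)),
        log = TRUE)
}

#' Poisson log-probability of an observed count
#'
#' Log-pmf of observing `n_obs` individuals in a survey of a fraction `f`
#' of the habitat when the true abundance is `n_true`: Poisson with mean
#' `f * n_true`. A positive count with zero true abundance is impossible
#' (`-Inf`).
#'
#' @param n_obs Observed count(s), nonnegative integer(s).
#' @param n_true True abundance(s), >= 0 (may be non-integer: latent
#'   states are continuous under the diffusion approximation).
#' @param f Search fraction in (0, 1].
#' @return Log-probability value(s).
#' @export
observation_logpmf <- function(n_obs, n_true, f) {
  stopifnot(all(n_obs >= 0), all(n_obs == round(n_obs)), all(n_true >= 0),
            f > 0, f <= 1)
  dpois(n_obs, lambda = f * n_true, log = TRUE)
}

#' Composite log-likelihood of an observation series
#'
#' Sum over surveys of (i) the Gaussian diffusion-approximation
#' transition term for the latent abundance and (ii) the Poisson
#' observation term for the recorded count given the latent abundance.
#' Two conditioning conventions are provided: `"markov"` (default)
#' conditions each latent state on the previous one over the elapsed
#' interval — the internally consistent state-space reading — while
#' `"origin"` evaluates every transition from the known introduction
#' size, making the latent states conditionally independent given the
#' parameters.
#'
#' A latent path that is nonpositive at any survey time is outside the
#' domain of the diffusion approximation and gets `-Inf`, which signals
#' proposal rejection in the sampler.
#'
#' @param obs An [observation_series()].
#' @param latent Latent true abundances at the `d` survey times (strictly
#'   positive reals); the introduction size is known and not part of it.
#' @param theta An [inference_params()] object.
#' @param mode `"markov"` or `"origin"` conditioning.
#' @param terms If `TRUE`, also return the per-survey Gaussian and
#'   Poisson contributions as attributes.
#'
#' @return The log-likelihood (scalar).
#' @export
loglikelihood <- function(obs, latent, theta, mode = c("markov", "origin"),
                          terms = FALSE) {
  stopifnot(inherits(obs, "observation_series"),
            inherits(theta, "inference_params"),
            length(latent) == obs$d)
  mode <- match.arg(mode)
  if (any(!is.finite(latent)) || any(latent <= 0)) return(-Inf)
  d <- obs$d
  if (mode == "markov") {
    n_from <- c(obs$n0, latent[-d])
    dt <- diff(obs$times)
  } else {
    n_from <- rep(obs$n0, d)
    dt <- obs$times[-1]
  }
  mv <- bdp_moments(n_from, dt, theta$lambda_bar, theta$mu, theta$N)
  if (any(!is.finite(mv$mean)) || any(!is.finite(mv$var))) return(-Inf)
  g <- dnorm(latent, mv$mean, sqrt(pmax(mv$var, .var_floor)), log = TRUE)
  p <- dpois(obs$counts[-1], lambda = obs$f * latent, log = TRUE)
  ll <- sum(g) + sum(p)
  if (terms) {
    attr(ll, "gaussian") <- g
    attr(ll, "poisson") <- p
  }
  ll
}
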