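#' Single-species demographic parameters
#'
#' Bundles the intrinsic per-capita birth rate \eqn{\lambda}, death rate
#' \eqn{\mu} and maximum population size \eqn{N} (the population size at
#' which the per-capita birth rate reaches zero) of one species, together
#' with the derived growth rate \eqn{r = \lambda - \mu} and carrying
#' capacity \eqn{K = r N / \lambda}. \eqn{K} is the deterministic
#' equilibrium; \eqn{N} is a physical habitat limit. The two coincide only
#' when \eqn{\mu = 0}.
#'
#' @param lambda Per-capita intrinsic birth rate (day^-1), > 0.
#' @param mu Per-capita intrinsic death rate (day^-1), >= 0.
#' @param N Maximum population size (individuals), > 0.
#'
#' @return An object of class `"species_params"`: a list with fields
#'   `lambda`, `mu`, `N`, `r`, `K`.
#' @export
#' @examples
#' species_params(lambda = 1.5, mu = 0.5, N = 15000)
species_params <- function(lambda, mu, N) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(N), length(N) == 1L, is.finite(N))
  if (lambda <= 0) stop("birth rate `lambda` must be > 0")
  if (mu < 0) stop("death rate `mu` must be >= 0")
  if (N <= 0) stop("maximum population size `N` must be > 0")
  r <- lambda - mu
  structure(
    list(lambda = lambda, mu = mu, N = N, r = r, K = r * N / lambda),
    class = "species_params"
  )
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species parameters (rates in day^-1):\n")
  cat(sprintf("  lambda = %g, mu = %g, N = %g\n", x$lambda, x$mu, x$N))
  cat(sprintf("  r = %g, K = %g\n", x$r, x$K))
  invisible(x)
}

#' Demographic parameters from the noise level delta
#'
#' The demographic-stochasticity control \eqn{\delta = (\lambda + \mu)/2}
#' sets the sum of the birth and death rates (the size of demographic
#' fluctuations) while keeping the mean dynamics fixed: with
#' \eqn{\lambda = \delta + 0.5}, \eqn{\mu = \delta - 0.5} and
#' \eqn{N = 10000 (\delta + 0.5)}, every \eqn{\delta} yields the same
#' growth rate \eqn{r = 1} day^-1 and carrying capacity \eqn{K = 10000}
#' individuals, so that varying \eqn{\delta} varies only the noise.
#'
#' @param delta Demographic noise coefficient (day^-1), >= 0.5 so that the
#'   death rate is nonnegative. The simulation experiments use
#'   \eqn{\delta \in [0.5, 5]}.
#'
#' @return A [species_params()] object with `r = 1` and `K = 10000`.
#' @export
#' @examples
#' params_from_delta(1)   # lambda = 1.5, mu = 0.5, N = 15000
params_from_delta <- function(delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (delta < 0.5) {
    stop("`delta` must be >= 0.5 (delta - 0.5 is the death rate)")
  }
  species_params(lambda = delta + 0.5, mu = delta - 0.5,
                 N = 10000 * (delta + 0.5))
}

#' Competition-modified (effective) invader parameters
#'
#' During the early stages of an introduction the resident community stays
#' very close to its carrying capacity \eqn{K_R}, so its competitive
#' pressure on the invader can be absorbed into a modified intrinsic birth
#' rate \deqn{\bar\lambda = \lambda (1 - \alpha K_R / N),} reducing the
#' two-species competition model to a one-species stochastic logistic
#' birth-death process with growth rate \eqn{\bar r = \bar\lambda - \mu}
#' and carrying capacity \eqn{\bar K = \bar r N / \bar\lambda}.
#'
#' A birth rate cannot be negative: when \eqn{\alpha K_R > N} the formula
#' is clipped to \eqn{\bar\lambda = 0} (a pure death process) and the
#' result is flagged via `clipped = TRUE`; `K_bar` is then `NaN` (the
#' carrying capacity of a pure death process is undefined).
#'
#' @param invader A [species_params()] object for the introduced species.
#' @param alpha Per-capita effect of the resident community on the invader
#'   (dimensionless), >= 0. `alpha = 1` is the deterministic bifurcation
#'   between establishment and extinction when \eqn{K_R = K_I}.
#' @param K_R Resident community carrying capacity (individuals), > 0.
#'
#' @return An object of class `"effective_params"`: a list with
#'   `lambda_bar`, `mu`, `N`, `r_bar`, `K_bar`, `clipped`.
#' @export
#' @examples
#' effective_params(params_from_delta(1), alpha = 0.5, K_R = 10000)
effective_params <- function(invader, alpha, K_R) {
  stopifnot(inherits(invader, "species_params"),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(K_R), length(K_R) == 1L, is.finite(K_R))
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (K_R <= 0) stop("`K_R` must be > 0")
  lambda_bar <- invader$lambda * (1 - alpha * K_R / invader$N)
  clipped <- lambda_bar < 0
  if (clipped) lambda_bar <- 0
  r_bar <- lambda_bar - invader$mu
  K_bar <- if (lambda_bar > 0) r_bar * invader$N / lambda_bar else NaN
  structure(
    list(lambda_bar = lambda_bar, mu = invader$mu, N = invader$N,
         r_bar = r_bar, K_bar = K_bar, clipped = clipped),
    class = "effective_params"
  )
}

#' @export
print.effective_params <- function(x, ...) {
  cat("Effective (competition-modified) invader parameters:\n")
  cat(sprintf("  lambda_bar = %g, mu = %g, N = %g\n", x$lambda_bar, x$mu, x$N))
  cat(sprintf("  r_bar = %g, K_bar = %g%s\n", x$r_bar, x$K_bar,
              if (isTRUE(x$clipped)) "  [birth rate clipped at 0]" else ""))
  invisible(x)
}

#' Mean of the logistic growth model
#'
#' Solution of \eqn{dn/dt = r n (1 - n/K)} from `n0`, evaluated in an
#' overflow-safe form so that large \eqn{|r t|} never produces `Inf`
#' intermediates. For `r = 0` the logistic solution at fixed `K` reduces
#' to the constant `n0`.
#'
#' @param t Time(s) (days), >= 0. Vectorised.
#' @param n0 Initial population size, >= 0.
#' @param r Growth rate (day^-1); may be negative.
#' @param K Carrying capacity, nonzero. Negative `K` arises for declining
#'   effective dynamics (\eqn{\bar r < 0}) and is handled.
#'
#' @return Numeric vector of population sizes.
#' @export
#' @examples
#' logistic_mean(4, n0 = 40, r = 1, K = 10000)  # ~1798.2
logistic_mean <- function(t, n0, r, K) {
  stopifnot(is.numeric(t), all(t >= 0), is.numeric(n0), length(n0) == 1L,
            n0 >= 0, is.numeric(r), length(r) == 1L,
            is.numeric(K), length(K) == 1L)
  if (n0 == 0) return(rep(0, length(t)))
  if (r == 0) return(rep(n0, length(t)))
  if (K == 0) stop("`K` must be nonzero when r != 0")
  if (r > 0) {
    # n0 / (e^{-rt} + (n0/K)(1 - e^{-rt})): bounded for t -> Inf
    emt <- exp(pmax(-r * t, -745))
    n0 / (emt + (n0 / K) * (1 - emt))
  } else {
    # decaying branch: e^{rt} -> 0, safe directly
    ert <- exp(pmin(r * t, 709))
    K * n0 * ert / (K + n0 * (ert - 1))
  }
}

#' Competition setup for a resident-invader pair
#'
#' Collects everything needed to simulate or solve the two-species
#' Lotka-Volterra competition system: the two species' demographic
#' parameters, the pairwise interaction coefficients, and initial sizes.
#' Defaults follow the standard introduction experiment: both species
#' parameterised by the same noise level `delta`, the resident starting at
#' its carrying capacity (10,000) and the invader introduced at 40
#' individuals, with the invader-on-resident effect fixed at 0.5.
#'
#' @param delta Demographic noise coefficient for both species.
#' @param alpha_IR Per-capita effect of the resident on the invader.
#' @param alpha_RI Per-capita effect of the invader on the resident.
#' @param n0_invader,n0_resident Initial population sizes (nonnegative
#'   integers).
#' @param invader,resident Optional [species_params()] overriding the
#'   `delta` parameterization.
#'
#' @return An object of class `"competition_setup"`.
#' @export
competition_setup <- function(delta = 1, alpha_IR = 0.5, alpha_RI = 0.5,
                              n0_invader = 40, n0_resident = 10000,
                              invader = NULL, resident = NULL) {
  if (is.null(invader)) invader <- params_from_delta(delta)
  if (is.null(resident)) resident <- params_from_delta(delta)
  stopifnot(inherits(invader, "species_params"),
            inherits(resident, "species_params"))
  if (alpha_IR < 0 || alpha_RI < 0) stop("interaction coefficients must be >= 0")
  if (n0_invader < 0 || n0_resident < 0 ||
      n0_invader != round(n0_invader) || n0_resident != round(n0_resident)) {
    stop("initial sizes must be nonnegative integers")
  }
  structure(
    list(invader = invader, resident = resident,
         alpha_IR = alpha_IR, alpha_RI = alpha_RI,
         n0_invader = as.integer(n0_invader),
         n0_resident = as.integer(n0_resident)),
    class = "competition_setup"
  )
}

#' Deterministic two-species Lotka-Volterra competition dynamics
#'
#' Integrates \deqn{dn_i/dt = r_i n_i (1 - (n_i + \alpha_{ij} n_j)/K_i)}
#' for the invader-resident pair with a stiff-capable solver at tight
#' tolerances. With both interaction coefficients zero each species
#' follows its own logistic curve.
#'
#' @param setup A [competition_setup()].
#' @param t_grid Increasing vector of times starting at 0 (days).
#' @param rtol,atol Solver tolerances passed to [deSolve::ode()].
#'
#' @return A data.frame with columns `t`, `n_I`, `n_R`.
#' @export
#' @examples
#' lv_deterministic(competition_setup(), t_grid = seq(0, 4, by = 0.5))
lv_deterministic <- function(setup, t_grid, rtol = 1e-10, atol = 1e-8) {
  stopifnot(inherits(setup, "competition_setup"),
            is.numeric(t_grid), length(t_grid) >= 2L,
            t_grid[1] == 0, all(diff(t_grid) > 0))
  pars <- c(rI = setup$invader$r, KI = setup$invader$K,
            rR = setup$resident$r, KR = setup$resident$K,
            aIR = setup$alpha_IR, aRI = setup$alpha_RI)
  deriv <- function(t, y, p) {
    dI <- p[["rI"]] * y[1] * (1 - (y[1] + p[["aIR"]] * y[2]) / p[["KI"]])
    dR <- p[["rR"]] * y[2] * (1 - (y[2] + p[["aRI"]] * y[1]) / p[["KR"]])
    list(c(dI, dR))
  }
  y0 <- c(nI = as.numeric(setup$n0_invader), nR = as.numeric(setup$n0_resident))
  sol <- deSolve::ode(y = y0, times = t_grid, func = deriv, parms = pars,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("Lotka-Volterra ODE solver failed to converge (istate = ",
         attr(sol, "istate")[1], ")")
  }
  out <- as.data.frame(sol)
  names(out) <- c("t", "n_I", "n_R")
  out
}

#' Deterministic outcome of an introduction
#'
#' In the reduced deterministic model the introduced species establishes
#' for interaction strength \eqn{\alpha < 1} and declines to extinction
#' for \eqn{\alpha > 1}; at \eqn{\alpha = 1} the system sits exactly on
#' the bifurcation and the outcome depends on initial conditions.
#' Comparisons are strict, with no epsilon band.
#'
#' @param alpha Interaction strength (resident on invader), >= 0.
#' @return One of `"ESTABLISH"`, `"EXTINCT"`, `"BIFURCATION"`.
#' @export
#' @examples
#' deterministic_outcome(0.5)
deterministic_outcome <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha < 0) stop("`alpha` must be >= 0")
  if (alpha < 1) "ESTABLISH" else if (alpha > 1) "EXTINCT" else "BIFURCATION"
}
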