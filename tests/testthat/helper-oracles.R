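# Closed-form oracles for the linear (density-independent) birth-death
# process and the pure death process, used as independent references for
# the simulator and the diffusion-approximation moments.

# P(extinct by t) for a linear pure death process (birth rate 0), n0
# independent individuals each dying at rate mu.
pure_death_extinction <- function(mu, t, n0) (1 - exp(-mu * t))^n0

# Mean and variance of a linear birth-death process with per-capita birth
# rate lb and death rate mu, started at n0.
linear_bd_mean <- function(n0, lb, mu, t) n0 * exp((lb - mu) * t)
linear_bd_var <- function(n0, lb, mu, t) {
  r <- lb - mu
  if (abs(r) < 1e-12) return(n0 * (lb + mu) * t)
  n0 * (lb + mu) / r * exp(r * t) * (exp(r * t) - 1)
}

# Standard error of a sample variance from the empirical fourth moment
# (large-n normal approximation, distribution-free).
var_se <- function(x) {
  n <- length(x)
  m <- mean(x)
  m4 <- mean((x - m)^4)
  v <- stats::var(x)
  sqrt((m4 - (n - 3) / (n - 1) * v^2) / n)
}

# Numerical marginal posterior of alpha for the origin-conditioned
# likelihood under ALL_FIXED: latent states are conditionally independent
# given theta, so each survey contributes a 1-D integral over its latent
# abundance, evaluated by trapezoidal quadrature. Independent of the MCMC
# code path (uses only the moment/density primitives).
alpha_posterior_oracle <- function(obs, delta, K_R = 10000,
                                   alpha_grid = seq(0.005, 1.995,
                                                    by = 0.005)) {
  p <- params_from_delta(delta)
  logpost <- vapply(alpha_grid, function(a) {
    th <- inference_params(r = p$r, K = p$K, N = p$N, K_R = K_R, alpha = a)
    mom <- transition_moments(rep(obs$n0, obs$d), obs$times[-1], th)
    sdv <- sqrt(pmax(mom$var, 0.25))
    ll <- 0
    for (i in seq_len(obs$d)) {
      lo <- max(mom$mean[i] - 8 * sdv[i], 1e-3)
      hi <- max(mom$mean[i] + 8 * sdv[i], lo + 1)
      nb <- seq(lo, hi, length.out = 400)
      integrand <- exp(dnorm(nb, mom$mean[i], sdv[i], log = TRUE) +
                         dpois(obs$counts[i + 1], obs$f * nb, log = TRUE))
      ll <- ll + log(sum((integrand[-1] + integrand[-400]) / 2 *
                           diff(nb)))
    }
    ll
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  list(grid = alpha_grid, weight = w,
       mean = sum(alpha_grid * w),
       mass_below_1 = sum(w[alpha_grid < 1]))
}
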