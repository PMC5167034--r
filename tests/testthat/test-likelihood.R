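theta_ref <- function(delta = 1, alpha = 0.5) {
  p <- params_from_delta(delta)
  inference_params(r = p$r, K = p$K, N = p$N, K_R = 10000, alpha = alpha)
}

test_that("inference parameterization recovers the defining identities", {
  th <- theta_ref(1, 0.5)
  expect_equal(th$lambda, 1.5)                   # r N / K
  expect_equal(th$mu, 0.5)
  expect_equal(th$lambda_bar, 1.0)
  expect_equal(th$r_bar, 0.5)
  expect_equal(th$K_bar, 7500)
  # mu = lambda_bar (N - K_bar) / N, the identity-consistent back-relation
  expect_equal(th$mu, th$lambda_bar * (th$N - th$K_bar) / th$N)
  expect_error(inference_params(1, 10000, 8000, 10000, 0.5), "N")
})

test_that("transition variance vanishes and mean is continuous as dt -> 0", {
  th <- theta_ref()
  mom <- transition_moments(40, 1e-8, th)
  expect_equal(mom$mean, 40, tolerance = 1e-6)
  expect_lt(mom$var, 1e-6 * 40)
})

test_that("variance approaches the linear birth-death law far from capacity", {
  th <- theta_ref(1, 0.5)  # lambda_bar 1, mu 0.5, r_bar 0.5
  mom <- transition_moments(40, 0.5, th)
  oracle <- linear_bd_var(40, 1.0, 0.5, 0.5)  # ~43.8
  expect_equal(mom$var, oracle, tolerance = 0.01)
})

test_that("closed-form and quadrature variance evaluations agree", {
  for (delta in c(1, 2.5, 4)) for (alpha in c(0.5, 1.5)) {
    th <- theta_ref(delta, alpha)
    for (dt in c(0.5, 2)) for (n0 in c(40, 2000)) {
      a <- transition_moments(n0, dt, th, method = "analytic")
      q <- transition_moments(n0, dt, th, method = "quadrature")
      expect_equal(a$var, q$var, tolerance = 1e-7)
    }
  }
})

test_that("quadrature is converged: halving the step leaves the variance", {
  for (delta in c(1, 4)) for (alpha in c(0.5, 1)) {
    th <- theta_ref(delta, alpha)
    v1 <- establishr:::.bdp_var_quad(40, 2, th$lambda_bar, th$mu, th$N,
                                     nodes = 201L, max_doublings = 0L)
    v2 <- establishr:::.bdp_var_quad(40, 2, th$lambda_bar, th$mu, th$N,
                                     nodes = 401L, max_doublings = 0L)
    expect_equal(v1, v2, tolerance = 1e-6)
  }
})

test_that("the r_bar = 0 ridge is handled without division by zero", {
  th <- theta_ref(1, 1)   # alpha = 1: lambda_bar = mu, r_bar = 0
  expect_equal(th$r_bar, 0)
  mom <- transition_moments(40, 1, th)
  expect_true(is.finite(mom$mean) && is.finite(mom$var))
  expect_equal(mom$mean, 40, tolerance = 0.01)     # K-form limit: ~constant
  # continuity across the ridge (the nearby point takes the closed form)
  near <- transition_moments(40, 1, theta_ref(1, 1 + 5e-3))
  expect_equal(mom$var, near$var, tolerance = 2e-2)
})

test_that("Gaussian transition density is a proper floored normal", {
  th <- theta_ref()
  mom <- transition_moments(40, 0.5, th)
  at_mode <- gaussian_logdensity(mom$mean, mom)
  expect_equal(at_mode, -0.5 * log(2 * pi * mom$var))
  expect_equal(gaussian_logdensity(mom$mean + 3, mom),
               gaussian_logdensity(mom$mean - 3, mom))
  # agreement with the explicit formula at arbitrary points
  for (x in c(10.5, 35, 52.2, 80, 140)) {
    manual <- -0.5 * log(2 * pi * mom$var) -
      (x - mom$mean)^2 / (2 * mom$var)
    expect_equal(gaussian_logdensity(x, mom), manual)
  }
  expect_error(gaussian_logdensity(NaN, mom), "non-finite")
})

test_that("Poisson observation term is a normalized pmf with the right mode", {
  expect_identical(observation_logpmf(0, 0, 0.25), 0)
  expect_identical(observation_logpmf(3, 0, 0.25), -Inf)
  lp <- observation_logpmf(0:600, 1000, 0.25)   # mean 250
  expect_equal(lp[250 + 1], max(lp))            # integer mean: tied mode
  expect_lt(abs(sum(exp(lp)) - 1), 1e-9)
})

test_that("log-likelihood assembles term by term", {
  obs <- observation_series(times = c(0, 0.4, 0.8, 1.2),
                            counts = c(40, 12, 14, 19), f = 0.25)
  th <- theta_ref(1, 0.5)
  latent <- c(45, 58, 70)
  # hand-summed from the two primitives, chaining moments manually
  hand <- 0
  from <- 40
  for (i in 1:3) {
    mom <- transition_moments(from, 0.4, th)
    hand <- hand + gaussian_logdensity(latent[i], mom) +
      observation_logpmf(obs$counts[i + 1], latent[i], 0.25)
    from <- latent[i]
  }
  expect_equal(loglikelihood(obs, latent, th), hand)
  # origin conditioning evaluates every transition from n0
  hand_o <- 0
  for (i in 1:3) {
    mom <- transition_moments(40, obs$times[i + 1], th)
    hand_o <- hand_o + gaussian_logdensity(latent[i], mom) +
      observation_logpmf(obs$counts[i + 1], latent[i], 0.25)
  }
  expect_equal(loglikelihood(obs, latent, th, mode = "origin"), hand_o)
  # inadmissible latent paths signal rejection
  expect_identical(loglikelihood(obs, c(45, -1, 70), th), -Inf)
  expect_identical(loglikelihood(obs, c(45, 0, 70), th), -Inf)
})

test_that("profile likelihood peaks near the generating interaction strength", {
  # long, dense, fully observed series: d = 50 over 10 days, f = 1
  delta <- 1; alpha_true <- 0.5
  eff <- effective_params(params_from_delta(delta), alpha_true, 10000)
  tt <- seq(0.2, 10, by = 0.2)
  tr <- simulate_invader(eff, 40, 10, seed = 4242, times = tt)
  obs <- observation_series(times = c(0, tt),
                            counts = c(40, observe_counts(tr$sizes, 1,
                                                          seed = 77)),
                            f = 1)
  latent <- pmax(tr$sizes, 1)
  grid <- seq(0.3, 0.7, by = 0.0025)
  prof <- vapply(grid, function(a)
    loglikelihood(obs, latent, theta_ref(delta, a)), numeric(1))
  expect_lt(abs(grid[which.max(prof)] - alpha_true), 0.05)
})
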