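test_that("prior scenarios free the right parameters", {
  an <- anchors_from_delta(1.75)
  expect_equal(an$r, 1)
  expect_equal(an$K, 10000)
  expect_equal(an$N, 22500)
  expect_identical(build_priors("ALL_FIXED", anchors = an)$free, "alpha")
  expect_identical(build_priors("PRIOR_K", 0.3, an)$free, c("alpha", "K"))
  expect_identical(build_priors("PRIOR_K_N", 0.3, an)$free,
                   c("alpha", "K", "N"))
  expect_identical(build_priors("PRIOR_K_N_R", 0.3, an)$free,
                   c("alpha", "K", "N", "r"))
  expect_error(build_priors("PRIOR_R", 0.3, an), "unknown scenario")
  expect_error(build_priors("PRIOR_K", 2, an), "sigma")
  # sigma = 0.01: 99% prior interval spans < 6% around the anchor
  q <- stats::qlnorm(c(0.005, 0.995), log(an$K), 0.01)
  expect_lt(q[2] / q[1], 1.06)
})

test_that("log posterior composes prior and likelihood", {
  obs <- simulate_observation_series(0.5, 1, seed = 5)
  an <- anchors_from_delta(1)
  latent <- pmax(obs$counts[-1] / obs$f, 1)
  th <- list(r = an$r, K = an$K, N = an$N, alpha = 0.6)
  # flat-prior region: posterior differences equal likelihood differences
  pf <- build_priors("ALL_FIXED", anchors = an)
  ip <- function(a) inference_params(an$r, an$K, an$N, an$K_R, a)
  d_post <- log_posterior(modifyList(th, list(alpha = 0.6)), latent, obs, pf) -
    log_posterior(modifyList(th, list(alpha = 0.9)), latent, obs, pf)
  d_lik <- loglikelihood(obs, latent, ip(0.6)) -
    loglikelihood(obs, latent, ip(0.9))
  expect_equal(d_post, d_lik)
  # out-of-support alpha is impossible
  expect_identical(log_posterior(modifyList(th, list(alpha = 2.5)),
                                 latent, obs, pf), -Inf)
  # a lognormal prior evaluated at its median adds a data-independent shift
  pk <- build_priors("PRIOR_K", 0.3, an)
  shift <- stats::dlnorm(an$K, log(an$K), 0.3, log = TRUE)
  expect_equal(log_posterior(th, latent, obs, pk),
               log_posterior(th, latent, obs, pf) + shift)
  obs2 <- simulate_observation_series(0.5, 1, seed = 6)
  expect_equal(log_posterior(th, latent, obs2, pk),
               log_posterior(th, latent, obs2, pf) + shift)
})

test_that("the random-walk kernel recovers a conjugate Gaussian posterior", {
  # known-variance Gaussian mean with Gaussian prior: closed-form posterior
  y <- c(4.1, 3.6, 5.2, 4.4, 3.9, 4.8, 4.3, 5.0)
  s2 <- 0.49; mu0 <- 3; tau2 <- 4
  post_var <- 1 / (length(y) / s2 + 1 / tau2)
  post_mean <- post_var * (sum(y) / s2 + mu0 / tau2)
  logpost <- function(m) sum(dnorm(y, m, sqrt(s2), log = TRUE)) +
    dnorm(m, mu0, sqrt(tau2), log = TRUE)
  set.seed(31)
  n <- 1e5
  draws <- numeric(n)
  st <- list(value = 4, lp = logpost(4))
  for (i in seq_len(n)) {
    st <- establishr:::rw_step(st$value, st$lp, 0.5, logpost)
    draws[i] <- st$value
  }
  draws <- draws[-(1:1000)]
  expect_equal(mean(draws), post_mean, tolerance = 0.02)
  expect_equal(stats::sd(draws), sqrt(post_var), tolerance = 0.02)
})

test_that("identical seeds give identical chains", {
  obs <- simulate_observation_series(0.8, 1.75, seed = 9)
  pr <- build_priors("PRIOR_K", 0.3, anchors_from_delta(1.75))
  f1 <- mh_sample(obs, pr, n_iter = 1200, n_burn = 300, thin = 3, seed = 8)
  f2 <- mh_sample(obs, pr, n_iter = 1200, n_burn = 300, thin = 3, seed = 8)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$accept, f2$accept)
  expect_identical(nrow(f1$draws), 300L)   # (n_iter - n_burn) / thin
})

test_that("posterior summaries report the tail masses and spread", {
  mk <- function(a) structure(list(
    draws = matrix(a, ncol = 1, dimnames = list(NULL, "alpha")),
    accept = c(alpha = 0.3), priors = list(scenario = "ALL_FIXED")),
    class = "posterior_sample")
  s <- posterior_summary(mk(c(0.2, 0.4, 0.6, 0.8)))
  expect_identical(s$mass_below_1, 1)
  expect_identical(s$mass_above_1, 0)
  s2 <- posterior_summary(mk(c(0.5, 0.7, 1.2, 1.4)))
  expect_identical(s2$mass_below_1, 0.5)
  expect_identical(s2$mass_above_1, 0.5)
  s3 <- posterior_summary(mk(rep(0.8, 50)))
  expect_identical(s3$se_alpha, 0)
  expect_equal(s3$mean_alpha, 0.8)
})

test_that("sampler agrees with a numerical-integration posterior oracle", {
  # origin conditioning + ALL_FIXED: latent states integrate out site by
  # site, so the alpha posterior has an independent quadrature solution
  obs <- simulate_observation_series(0.8, 1.75, seed = 1234)
  oracle <- alpha_posterior_oracle(obs, 1.75)
  pr <- build_priors("ALL_FIXED", anchors = anchors_from_delta(1.75))
  fit <- mh_sample(obs, pr, n_iter = 24000, n_burn = 6000, thin = 3,
                   seed = 55, mode = "origin")
  s <- posterior_summary(fit)
  expect_lt(abs(s$mean_alpha - oracle$mean), 0.03)
  expect_lt(abs(s$mass_below_1 - oracle$mass_below_1), 0.05)
})

test_that("posterior concentrates on the correct side of the bifurcation", {
  obs <- simulate_observation_series(0.5, 1, seed = 21)
  pr <- build_priors("ALL_FIXED", anchors = anchors_from_delta(1))
  fit <- mh_sample(obs, pr, n_iter = 6000, n_burn = 2000, thin = 4,
                   seed = 22)
  expect_gt(posterior_summary(fit)$mass_below_1, 0.5)
})

test_that("credible intervals cover the generating value at small data", {
  n_fit <- 15
  for (alpha_true in c(0.5, 1.5)) {
    covered <- 0L
    for (i in seq_len(n_fit)) {
      seed <- substream_seed(1000 + 10 * alpha_true, i)
      obs <- simulate_observation_series(alpha_true, 1, seed = seed)
      pr <- build_priors("ALL_FIXED", anchors = anchors_from_delta(1))
      fit <- mh_sample(obs, pr, n_iter = 6000, n_burn = 2000, thin = 4,
                       seed = seed + 1)
      ci <- posterior_summary(fit)$ci95
      covered <- covered + (ci[1] <= alpha_true && alpha_true <= ci[2])
    }
    expect_gte(covered, 11L)  # ~ nominal coverage, small-data regime
  }
})

test_that("posterior spread of alpha grows with the prior width", {
  ses <- vapply(c(0.1, 1), function(sg) {
    pr <- build_priors("PRIOR_K_N_R", sg, anchors_from_delta(1.75))
    mean(vapply(1:6, function(i) {
      seed <- substream_seed(777, i)
      obs <- simulate_observation_series(0.8, 1.75, seed = seed)
      fit <- mh_sample(obs, pr, n_iter = 6000, n_burn = 2000, thin = 4,
                       seed = seed + 3)
      posterior_summary(fit)$se_alpha
    }, numeric(1)))
  }, numeric(1))
  expect_gt(ses[2], ses[1])
})

test_that("wide priors bias the interaction estimate downward", {
  pr <- build_priors("PRIOR_K_N_R", 1, anchors_from_delta(0.75))
  means <- vapply(1:6, function(i) {
    seed <- substream_seed(888, i)
    obs <- simulate_observation_series(1.5, 0.75, seed = seed)
    fit <- mh_sample(obs, pr, n_iter = 6000, n_burn = 2000, thin = 4,
                     seed = seed + 3)
    posterior_summary(fit)$mean_alpha
  }, numeric(1))
  expect_lt(mean(means), 1.5)
})

test_that("chains are healthy at default settings", {
  obs <- simulate_observation_series(0.8, 1.75, seed = 333)
  pr <- build_priors("ALL_FIXED", anchors = anchors_from_delta(1.75))
  fit <- mh_sample(obs, pr, seed = 334)   # 30000 / 10000 / 5 defaults
  s <- posterior_summary(fit)
  expect_true(all(fit$accept >= 0.1 & fit$accept <= 0.6))
  expect_gte(s$ess_alpha, 200)
})
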