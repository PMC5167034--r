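test_that("pure-death regime matches the closed-form extinction law", {
  # delta = 1, alpha = 1.5 zeroes the birth rate: linear death process
  eff <- effective_params(params_from_delta(1), 1.5, 10000)
  expect_equal(eff$lambda_bar, 0)
  n_reps <- 10000
  ext4 <- logical(n_reps)
  ext10 <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    tr <- simulate_invader(eff, 40, 10, seed = substream_seed(5, i),
                           times = c(4, 10))
    ext4[i] <- tr$sizes[1] == 0L
    ext10[i] <- tr$sizes[2] == 0L
  }
  p4 <- pure_death_extinction(0.5, 4, 40)     # ~0.0030
  p10 <- pure_death_extinction(0.5, 10, 40)   # ~0.763
  expect_lt(abs(mean(ext4) - p4), 3 * sqrt(p4 * (1 - p4) / n_reps))
  expect_lt(abs(mean(ext10) - p10), 3 * sqrt(p10 * (1 - p10) / n_reps))
  expect_true(all(ext10[ext4]))               # absorption is permanent
})

test_that("zero death rate makes extinction impossible", {
  eff <- effective_params(params_from_delta(0.5), 0.5, 10000)
  expect_identical(eff$mu, 0)
  ens <- simulate_ensemble(eff, n0 = 40, times = c(2, 5, 10), n_reps = 500,
                           master_seed = 3)
  expect_identical(ens$extinct_frac, c(0, 0, 0))
})

test_that("ensemble mean follows the effective logistic curve", {
  eff <- effective_params(params_from_delta(1), 0.5, 10000)
  ens <- simulate_ensemble(eff, n0 = 40, times = c(1, 2, 4), n_reps = 10000,
                           master_seed = 11)
  expected <- logistic_mean(c(1, 2, 4), 40, eff$r_bar, eff$K_bar)
  se <- sqrt(ens$var / attr(ens, "n_reps"))
  expect_true(all(abs(ens$mean - expected) < 3 * se))
})

test_that("linear-regime moments match the linear birth-death closed forms", {
  n_reps <- 10000
  for (delta in c(1, 4)) {
    eff <- effective_params(params_from_delta(delta), 0.5, 10000)
    times <- c(0.5, 1)
    sizes <- matrix(0L, n_reps, 2)
    for (i in seq_len(n_reps)) {
      tr <- simulate_invader(eff, 40, 1, seed = substream_seed(delta, i),
                            times = times)
      sizes[i, ] <- tr$sizes
    }
    for (j in 1:2) {
      m_th <- linear_bd_mean(40, eff$lambda_bar, eff$mu, times[j])
      v_th <- linear_bd_var(40, eff$lambda_bar, eff$mu, times[j])
      expect_lt(abs(mean(sizes[, j]) - m_th),
                3 * stats::sd(sizes[, j]) / sqrt(n_reps))
      expect_lt(abs(stats::var(sizes[, j]) - v_th), 3 * var_se(sizes[, j]))
    }
  }
})

test_that("identical seeds give bit-identical trajectories and counts", {
  eff <- effective_params(params_from_delta(2.5), 0.8, 10000)
  a <- simulate_invader(eff, 40, 4, seed = 99, times = seq(0.4, 4, 0.4),
                        keep_events = TRUE)
  b <- simulate_invader(eff, 40, 4, seed = 99, times = seq(0.4, 4, 0.4),
                        keep_events = TRUE)
  expect_identical(a$sizes, b$sizes)
  expect_identical(a$events, b$events)
  expect_identical(observe_counts(a$sizes, 0.25, seed = 1),
                   observe_counts(b$sizes, 0.25, seed = 1))
  e1 <- simulate_ensemble(eff, n0 = 40, times = c(1, 4), n_reps = 50,
                          master_seed = 4)
  e2 <- simulate_ensemble(eff, n0 = 40, times = c(1, 4), n_reps = 50,
                          master_seed = 4)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
})

test_that("clamped pair simulation reduces exactly to the one-species chain", {
  setup <- competition_setup(delta = 1, alpha_IR = 0.5)
  eff <- effective_params(setup$invader, 0.5, setup$resident$K)
  tt <- seq(0.5, 4, 0.5)
  for (s in c(7, 21, 303)) {
    pa <- simulate_pair(setup, 4, seed = s, times = tt, mode = "clamped")
    si <- simulate_invader(eff, 40, 4, seed = s, times = tt)
    expect_identical(pa$sizes, si$sizes)
    expect_identical(pa$sizes_resident, rep(10000, length(tt)))
  }
})

test_that("joint simulation keeps the resident within 1% of its capacity", {
  setup <- competition_setup(delta = 1, alpha_IR = 0.5, alpha_RI = 0.5)
  ens <- simulate_ensemble(setup, times = c(1, 2, 3, 4), n_reps = 100,
                           master_seed = 17, mode = "joint")
  expect_true(all(ens$mean_resident >= 0.99 * 10000))
})

test_that("piecewise-constant lookup respects event structure and absorption", {
  eff <- effective_params(params_from_delta(1), 1.5, 10000)  # pure death
  tr <- simulate_invader(eff, 5, 50, seed = 12, keep_events = TRUE)
  expect_true(tr$extinct)
  expect_identical(sample_at_times(tr, 0), 5L)
  ev <- tr$events
  mid <- (ev$times[2] + ev$times[3]) / 2   # strictly between two events
  expect_identical(sample_at_times(tr, mid), ev$sizes[2])
  expect_identical(sample_at_times(tr, 49.9), 0L)
  expect_error(sample_at_times(tr, 51), "outside")
  no_ev <- simulate_invader(eff, 5, 1, seed = 12)
  expect_error(sample_at_times(no_ev, 0.5), "keep_events")
})

test_that("observation model is Poisson thinning with mean f * n", {
  expect_identical(observe_counts(rep(0, 10), 0.25, seed = 1), rep(0L, 10))
  x <- observe_counts(rep(1000, 1e5), 0.25, seed = 2)
  expect_lt(abs(mean(x) - 250), 3 * stats::sd(x) / sqrt(1e5))
  y <- observe_counts(rep(400, 1e5), 1, seed = 3)
  expect_lt(abs(mean(y) - 400), 3 * stats::sd(y) / sqrt(1e5))
  expect_lt(abs(stats::var(y) - 400), 3 * var_se(y))
  expect_error(observe_counts(100, 0), "f")
})
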