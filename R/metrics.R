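#' Predictability of the establishment outcome
#'
#' The probability that a stochastic realization shows, at time `t`, the
#' same extant/extinct status as the deterministic model predicts for the
#' given interaction strength: extinction means the population is exactly
#' 0 at `t` (the absorbing state), establishment means it is not.
#' Estimated as the matching fraction over `n_reps` clamped-resident
#' Gillespie replicates, each with its own substream seed. At the
#' bifurcation (`alpha = 1`, where the deterministic model is marginal)
#' replicates are scored against establishment and the result is flagged
#' via the `"bifurcation"` attribute.
#'
#' @param alpha Interaction strength.
#' @param delta Demographic noise coefficient.
#' @param t Evaluation time (days).
#' @param n_reps Number of replicates (>= 1).
#' @param n0 Introduction size (default 40).
#' @param K_R Resident carrying capacity (default 10000).
#' @param seed Master seed for the replicate substreams.
#' @return Matching probability in `[0, 1]`.
#' @export
#' @examples
#' predictability(alpha = 0.5, delta = 1, t = 4, n_reps = 200, seed = 1)
predictability <- function(alpha, delta, t, n_reps = 100, n0 = 40,
                           K_R = 10000, seed = NULL) {
  stopifnot(n_reps >= 1)
  outcome <- deterministic_outcome(alpha)
  eff <- effective_params(params_from_delta(delta), alpha, K_R)
  extinct <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    s <- if (is.null(seed)) NULL else substream_seed(seed, i, "predictability")
    tr <- simulate_invader(eff, n0, t_end = t, seed = s, times = t)
    extinct[i] <- tr$sizes[1] == 0L
  }
  value <- if (outcome == "EXTINCT") mean(extinct) else mean(!extinct)
  structure(value, bifurcation = identical(outcome, "BIFURCATION"))
}

#' Predictability map over the (alpha, delta) plane
#'
#' Element-wise [predictability()] over a grid of interaction strengths
#' and noise levels, at one or more evaluation times, with per-pixel
#' seeds derived from the master seed so any pixel can be re-run in
#' isolation.
#'
#' @param alphas,deltas Strictly increasing grid values.
#' @param times Evaluation times (days), default `c(4, 6, 8, 10)`.
#' @param n_reps Replicates per pixel (default 100).
#' @param n0,K_R As in [predictability()].
#' @param seed Master seed.
#' @return A data.frame of class `"metric_map"` in long format:
#'   `alpha, delta, t, value, n_reps, seed`.
#' @export
predictability_map <- function(alphas, deltas, times = c(4, 6, 8, 10),
                               n_reps = 100, n0 = 40, K_R = 10000,
                               seed = 1) {
  stopifnot(all(diff(alphas) > 0) || length(alphas) == 1L,
            all(diff(deltas) > 0) || length(deltas) == 1L)
  grid <- expand.grid(alpha = alphas, delta = deltas, t = times,
                      KEEP.OUT.ATTRS = FALSE)
  grid$value <- NA_real_
  grid$n_reps <- n_reps
  grid$seed <- NA_integer_
  # one trajectory set per (alpha, delta) pixel, evaluated at all times
  ad <- unique(grid[, c("alpha", "delta")])
  for (k in seq_len(nrow(ad))) {
    a <- ad$alpha[k]; de <- ad$delta[k]
    px_seed <- substream_seed(seed, k, "pixel")
    eff <- effective_params(params_from_delta(de), a, K_R)
    ext <- matrix(FALSE, n_reps, length(times))
    for (i in seq_len(n_reps)) {
      s <- substream_seed(px_seed, i, "predictability")
      tr <- simulate_invader(eff, n0, t_end = max(times), seed = s,
                             times = times)
      ext[i, ] <- tr$sizes == 0L
    }
    for (j in seq_along(times)) {
      sel <- grid$alpha == a & grid$delta == de & grid$t == times[j]
      grid$value[sel] <- if (deterministic_outcome(a) == "EXTINCT") {
        mean(ext[, j])
      } else {
        mean(!ext[, j])
      }
      grid$seed[sel] <- px_seed
    }
  }
  structure(grid, class = c("metric_map", "data.frame"),
            metric = "predictability", n0 = n0, K_R = K_R,
            master_seed = seed)
}

#' Predictive ability of one posterior
#'
#' The posterior probability mass of the interaction strength lying on
#' the same side of the bifurcation (`alpha = 1`) as the generating
#' value: the proportion of predictions that call the deterministic
#' outcome correctly.
#'
#' @param posterior A [mh_sample()] result (or `posterior_summary`).
#' @param true_alpha Generating interaction strength (must not be 1).
#' @return Probability in `[0, 1]`.
#' @export
predictive_ability <- function(posterior, true_alpha) {
  if (true_alpha == 1) {
    stop("predictive ability is undefined at the bifurcation (alpha = 1)")
  }
  s <- if (inherits(posterior, "posterior_summary")) posterior
       else posterior_summary(posterior)
  if (true_alpha < 1) s$mass_below_1 else s$mass_above_1
}

# Shared protocol of the inference experiments: simulate one introduction
# data set and fit it under the given prior scenario.
fit_one_introduction <- function(alpha, delta, priors, seed, n0 = 40,
                                 d = 10, t_max = 4, f = 0.25, K_R = 10000,
                                 n_iter = 20000, n_burn = 6000, thin = 4,
                                 mode = "markov") {
  obs <- simulate_observation_series(alpha, delta, n0 = n0, d = d,
                                     t_max = t_max, f = f, K_R = K_R,
                                     seed = substream_seed(seed, 0L, "data"))
  mh_sample(obs, priors, n_iter = n_iter, n_burn = n_burn, thin = thin,
            seed = substream_seed(seed, 0L, "mcmc"), mode = mode)
}

#' Mean predictive ability at one (alpha, delta) pixel
#'
#' The full inference experiment behind each pixel of the
#' predictive-ability map: simulate `n_real` replicate introductions
#' (clamped resident), observe each on the standard survey schedule, run
#' the Metropolis-Hastings sampler under the given prior scenario, and
#' average the per-replicate posterior mass on the correct side of the
#' bifurcation (a mean over realizations, not a majority vote).
#'
#' @param alpha,delta Generating interaction strength (not 1) and noise
#'   level.
#' @param scenario,sigma Prior scenario and width ([build_priors()]).
#' @param n_real Number of replicate introductions (default 30).
#' @param seed Master seed.
#' @param n0,d,t_max,f,K_R Observation protocol (defaults: 40
#'   individuals, 10 surveys over 4 days, search fraction 0.25).
#' @param n_iter,n_burn,thin Chain settings per fit.
#' @return Mean predictive ability, with per-replicate values in the
#'   `"replicates"` attribute.
#' @export
predictive_ability_pixel <- function(alpha, delta, scenario = "ALL_FIXED",
                                     sigma = 0.3, n_real = 30, seed = 1,
                                     n0 = 40, d = 10, t_max = 4, f = 0.25,
                                     K_R = 10000, n_iter = 20000,
                                     n_burn = 6000, thin = 4) {
  if (alpha == 1) stop("pixel at the bifurcation has no correct side")
  priors <- build_priors(scenario, sigma = sigma,
                         anchors = anchors_from_delta(delta, K_R))
  pa <- numeric(n_real)
  for (i in seq_len(n_real)) {
    fit <- fit_one_introduction(alpha, delta, priors,
                                seed = substream_seed(seed, i, "realization"),
                                n0 = n0, d = d, t_max = t_max, f = f,
                                K_R = K_R, n_iter = n_iter, n_burn = n_burn,
                                thin = thin)
    pa[i] <- predictive_ability(fit, alpha)
  }
  structure(mean(pa), replicates = pa)
}

#' Predictive-ability map over the (alpha, delta) plane
#'
#' Element-wise [predictive_ability_pixel()] on a grid (bifurcation
#' pixels `alpha = 1` are excluded: there is no correct side to score).
#' Per-pixel inference failures are caught, flagged with `NA` and
#' reported, never silently dropped.
#'
#' @inheritParams predictive_ability_pixel
#' @param alphas,deltas Grid values (`alphas` must avoid 1).
#' @return A long-format `"metric_map"` data.frame.
#' @export
predictive_ability_map <- function(alphas, deltas, scenario = "ALL_FIXED",
                                   sigma = 0.3, n_real = 30, seed = 1,
                                   n0 = 40, d = 10, t_max = 4, f = 0.25,
                                   K_R = 10000, n_iter = 20000,
                                   n_burn = 6000, thin = 4) {
  alphas <- alphas[alphas != 1]
  grid <- expand.grid(alpha = alphas, delta = deltas, t = t_max,
                      KEEP.OUT.ATTRS = FALSE)
  grid$value <- NA_real_
  grid$n_reps <- n_real
  grid$seed <- NA_integer_
  for (k in seq_len(nrow(grid))) {
    px_seed <- substream_seed(seed, k, "pixel")
    grid$seed[k] <- px_seed
    val <- tryCatch(
      predictive_ability_pixel(grid$alpha[k], grid$delta[k],
                               scenario = scenario, sigma = sigma,
                               n_real = n_real, seed = px_seed, n0 = n0,
                               d = d, t_max = t_max, f = f, K_R = K_R,
                               n_iter = n_iter, n_burn = n_burn,
                               thin = thin),
      error = function(e) {
        warning(sprintf("pixel (alpha=%g, delta=%g) failed: %s",
                        grid$alpha[k], grid$delta[k], conditionMessage(e)))
        NA_real_
      })
    grid$value[k] <- as.numeric(val)
  }
  structure(grid, class = c("metric_map", "data.frame"),
            metric = "predictive_ability", scenario = scenario,
            sigma = sigma, master_seed = seed)
}

#' Precision and accuracy of the interaction-strength estimate
#'
#' Averaged over replicate posteriors: the posterior standard deviation
#' of `alpha` (precision, also reported on the log scale) and the
#' absolute distance between the posterior mean and the generating value
#' (accuracy).
#'
#' @param posteriors List of [mh_sample()] results (or summaries).
#' @param true_alpha Generating interaction strength.
#' @return List with `se`, `log_se`, `abs_error`.
#' @export
precision_accuracy <- function(posteriors, true_alpha) {
  stopifnot(length(posteriors) >= 1)
  sums <- lapply(posteriors, function(p) {
    if (inherits(p, "posterior_summary")) p else posterior_summary(p)
  })
  se <- mean(vapply(sums, `[[`, numeric(1), "se_alpha"))
  abs_err <- mean(vapply(sums, function(s) abs(s$mean_alpha - true_alpha),
                         numeric(1)))
  list(se = se, log_se = log(se), abs_error = abs_err)
}

#' Precision/accuracy sweep over the prior width
#'
#' For each prior width `sigma`, fit `n_real` replicate introductions
#' under the given scenario and report the averaged precision and
#' accuracy of the `alpha` estimate.
#'
#' @inheritParams predictive_ability_pixel
#' @param sigmas Prior widths to sweep (in `[0.01, 1]`).
#' @return data.frame with columns `sigma`, `se`, `log_se`, `abs_error`,
#'   `rel_se` (SE divided by `true_alpha`).
#' @export
precision_sweep <- function(sigmas, alpha, delta, scenario = "PRIOR_K",
                            n_real = 30, seed = 1, n0 = 40, d = 10,
                            t_max = 4, f = 0.25, K_R = 10000,
                            n_iter = 12000, n_burn = 4000, thin = 4) {
  out <- data.frame(sigma = sigmas, se = NA_real_, log_se = NA_real_,
                    abs_error = NA_real_, rel_se = NA_real_)
  for (k in seq_along(sigmas)) {
    priors <- build_priors(scenario, sigma = sigmas[k],
                           anchors = anchors_from_delta(delta, K_R))
    fits <- vector("list", n_real)
    for (i in seq_len(n_real)) {
      fits[[i]] <- fit_one_introduction(
        alpha, delta, priors,
        seed = substream_seed(seed, k * 100000L + i, "sweep"),
        n0 = n0, d = d, t_max = t_max, f = f, K_R = K_R,
        n_iter = n_iter, n_burn = n_burn, thin = thin)
    }
    pa <- precision_accuracy(fits, alpha)
    out$se[k] <- pa$se
    out$log_se[k] <- pa$log_se
    out$abs_error[k] <- pa$abs_error
    out$rel_se[k] <- pa$se / alpha
  }
  out
}

#' Difference of two metric maps
#'
#' Element-wise `a - b` on identical grids (e.g. predictability minus
#' predictive ability); negative values are meaningful — inference can
#' out-predict raw predictability in the extinction half-plane.
#'
#' @param a,b `"metric_map"` data.frames on the same grid.
#' @return A `"metric_map"` of differences.
#' @export
map_difference <- function(a, b) {
  stopifnot(inherits(a, "metric_map"), inherits(b, "metric_map"))
  key <- c("alpha", "delta", "t")
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a[key], b[key],
                                              check.attributes = FALSE))) {
    stop("maps are on different grids")
  }
  out <- a
  out$value <- a$value - b$value
  attr(out, "metric") <- paste0(attr(a, "metric"), " - ", attr(b, "metric"))
  out
}
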