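# One scalar random-walk Metropolis step. `lp_fn` evaluates the target
# log-density at the candidate; non-finite candidates are rejected. The
# same accept/reject kernel drives every parameter block of mh_sample, so
# its correctness is testable on analytically tractable targets.
rw_step <- function(value, lp, prop_sd, lp_fn) {
  cand <- value + prop_sd * rnorm(1L)
  lp2 <- lp_fn(cand)
  if (is.finite(lp2) && log(runif(1L)) < lp2 - lp) {
    list(value = cand, lp = lp2, accepted = TRUE)
  } else {
    list(value = value, lp = lp, accepted = FALSE)
  }
}

#' Metropolis-Hastings sampling of the establishment posterior
#'
#' Samples the joint posterior of the free model parameters and the
#' latent true abundances given an observed introduction time series.
#' Free parameters are determined by the prior scenario: `alpha` always
#' (random walk on the natural scale, flat prior on its support), and any
#' of `K`, `N`, `r` carrying lognormal priors (random walk on the log
#' scale, where the prior is normal). Latent abundances are updated by
#' single-site multiplicative (log-scale) random walks, swept as two
#' alternating blocks of conditionally independent sites per iteration.
#'
#' Proposal step sizes adapt in batches of 50 iterations during burn-in
#' only (targeting 20-40% acceptance per block), so detailed balance
#' holds for every retained draw.
#'
#' @param obs An [observation_series()].
#' @param priors A [build_priors()] object.
#' @param init Optional named list of initial values (`alpha`, `K`, `N`,
#'   `r`, `latent`). Defaults: parameters at their anchors, `alpha` at
#'   the midpoint 1, latent at `pmax(counts / f, 1)`.
#' @param n_iter Total iterations (default 30000).
#' @param n_burn Burn-in iterations discarded (default 10000).
#' @param thin Thinning interval for retained draws (default 5).
#' @param seed Optional integer seed; chains with the same seed are
#'   identical.
#' @param mode Likelihood conditioning convention ([loglikelihood()]).
#' @param keep_latent If `TRUE`, retain thinned latent-state draws.
#'
#' @return An object of class `"posterior_sample"`: list with `draws`
#'   (matrix, one column per free parameter), optional `latent_draws`,
#'   `accept` (per-block post-burn-in acceptance rates), `settings` and
#'   `priors`.
#' @export
#' @examples
#' obs <- simulate_observation_series(alpha = 0.5, delta = 1, seed = 1)
#' pr <- build_priors("ALL_FIXED", anchors = anchors_from_delta(1))
#' fit <- mh_sample(obs, pr, n_iter = 2000, n_burn = 500, thin = 5, seed = 2)
#' posterior_summary(fit)
mh_sample <- function(obs, priors, init = NULL, n_iter = 30000,
                      n_burn = 10000, thin = 5, seed = NULL,
                      mode = c("markov", "origin"), keep_latent = FALSE) {
  stopifnot(inherits(obs, "observation_series"),
            inherits(priors, "prior_spec"),
            n_iter > n_burn, n_burn >= 0, thin >= 1)
  mode <- match.arg(mode)
  with_seed(seed, .mh_sample_impl(obs, priors, init, as.integer(n_iter),
                                  as.integer(n_burn), as.integer(thin),
                                  mode, keep_latent, seed))
}

.mh_sample_impl <- function(obs, priors, init, n_iter, n_burn, thin, mode,
                            keep_latent, seed) {
  d <- obs$d
  dt_mk <- diff(obs$times)
  t_or <- obs$times[-1]
  cnt <- obs$counts[-1]
  f <- obs$f
  n0 <- obs$n0
  anch <- priors$anchors
  markov <- mode == "markov"

  free <- priors$free
  par <- c(alpha = 1.0, r = anch$r, K = anch$K, N = anch$N)
  if (!is.null(init)) {
    for (p in intersect(names(init), names(par))) par[[p]] <- init[[p]]
  }
  latent <- pmax(cnt / f, 1)
  if (!is.null(init$latent)) latent <- init$latent

  rates_of <- function(par) {
    if (par[["N"]] < par[["K"]]) return(NULL)
    rt <- derive_rates(par[["r"]], par[["K"]], par[["N"]], anch$K_R,
                       par[["alpha"]])
    rt$N <- par[["N"]]
    rt
  }
  # Gaussian transition terms for the full latent path under rates `rt`
  gvec <- function(lat, rt) {
    if (markov) {
      mv <- bdp_moments(c(n0, lat[-d]), dt_mk, rt$lambda_bar, rt$mu, rt$N)
    } else {
      mv <- bdp_moments(rep.int(n0, d), t_or, rt$lambda_bar, rt$mu, rt$N)
    }
    if (any(!is.finite(mv$mean)) || any(!is.finite(mv$var))) return(NULL)
    dnorm(lat, mv$mean, sqrt(pmax(mv$var, .var_floor)), log = TRUE)
  }
  # Normal log priors on the log scale (= lognormal on the natural scale)
  wp <- priors$with_prior
  log_anch <- if (length(wp)) log(unlist(anch[wp])) else numeric(0)
  sig <- priors$sigma
  alo <- priors$alpha_support[1]
  ahi <- priors$alpha_support[2]
  prior_lp <- function(par) {
    a <- par[["alpha"]]
    if (a < alo || a > ahi) return(-Inf)
    if (!length(wp)) return(0)
    sum(dnorm(log(par[wp]), log_anch, sig, log = TRUE))
  }

  rt <- rates_of(par)
  g <- gvec(latent, rt)
  if (is.null(g)) stop("initial state has an invalid likelihood")
  pv <- dpois(cnt, f * latent, log = TRUE)
  lp_prior <- prior_lp(par)
  lp_par <- sum(g) + lp_prior            # Poisson terms constant in theta

  odd <- seq(1L, d, by = 2L)
  even <- if (d >= 2L) seq(2L, d, by = 2L) else integer(0)

  steps <- c(alpha = 0.25, r = 0.15, K = 0.2, N = 0.2)
  step_lat <- rep(0.4, d)
  acc_par <- structure(numeric(length(free)), names = free)
  try_par <- acc_par
  acc_lat <- numeric(d)
  try_lat <- numeric(d)
  bat_acc_par <- acc_par; bat_try_par <- try_par
  bat_acc_lat <- acc_lat; bat_try_lat <- try_lat

  n_keep <- (n_iter - n_burn) %/% thin
  draws <- matrix(NA_real_, n_keep, length(free),
                  dimnames = list(NULL, free))
  lat_draws <- if (keep_latent) matrix(NA_real_, n_keep, d) else NULL
  ki <- 0L

  # Candidate evaluators, one closure per free parameter, created once;
  # they read the current state (par, latent) from this environment and
  # deposit the candidate Gaussian-term vector in g_cand on success.
  g_cand <- NULL
  lp_fns <- vector("list", length(free))
  names(lp_fns) <- free
  for (p in free) {
    lp_fns[[p]] <- local({
      pp <- p
      on_log <- p != "alpha"
      function(cand) {
        par2 <- par
        par2[[pp]] <- if (on_log) exp(cand) else cand
        rt2 <- rates_of(par2)
        if (is.null(rt2)) return(-Inf)
        lpp <- prior_lp(par2)
        if (!is.finite(lpp)) return(-Inf)
        g2 <- gvec(latent, rt2)
        if (is.null(g2)) return(-Inf)
        g_cand <<- g2
        sum(g2) + lpp
      }
    })
  }

  for (it in seq_len(n_iter)) {
    in_burn <- it <= n_burn
    ## --- parameter blocks ---
    for (p in free) {
      cur_val <- if (p == "alpha") par[["alpha"]] else log(par[[p]])
      st <- rw_step(cur_val, lp_par, steps[[p]], lp_fns[[p]])
      bat_try_par[[p]] <- bat_try_par[[p]] + 1
      if (!in_burn) try_par[[p]] <- try_par[[p]] + 1
      if (st$accepted) {
        par[[p]] <- if (p == "alpha") st$value else exp(st$value)
        rt <- rates_of(par)
        g <- g_cand
        lp_par <- st$lp
        lp_prior <- prior_lp(par)
        bat_acc_par[[p]] <- bat_acc_par[[p]] + 1
        if (!in_burn) acc_par[[p]] <- acc_par[[p]] + 1
      }
    }

    ## --- latent blocks (odd sites, then even: conditionally independent) ---
    for (blk in list(odd, even)) {
      if (!length(blk)) next
      nb <- length(blk)
      lat2b <- latent[blk] * exp(step_lat[blk] * rnorm(nb))
      # terms i: transition into site i (n_from unchanged)
      from_i <- if (markov) c(n0, latent)[blk] else rep.int(n0, nb)
      dt_i <- if (markov) dt_mk[blk] else t_or[blk]
      mv_i <- bdp_moments(from_i, dt_i, rt$lambda_bar, rt$mu, rt$N)
      g_i_new <- dnorm(lat2b, mv_i$mean,
                       sqrt(pmax(mv_i$var, .var_floor)), log = TRUE)
      # terms i+1: transition out of site i (markov mode only)
      nxt <- blk + 1L
      has_nxt <- markov & nxt <= d
      g_n_new <- numeric(nb)
      g_n_old <- numeric(nb)
      if (any(has_nxt)) {
        j <- which(has_nxt)
        mv_n <- bdp_moments(lat2b[j], dt_mk[nxt[j]], rt$lambda_bar, rt$mu,
                            rt$N)
        g_n_new[j] <- dnorm(latent[nxt[j]], mv_n$mean,
                            sqrt(pmax(mv_n$var, .var_floor)), log = TRUE)
        g_n_old[j] <- g[nxt[j]]
      }
      p_new <- dpois(cnt[blk], f * lat2b, log = TRUE)
      # log-scale random walk on latent with flat prior in natural scale:
      # Jacobian term log(lat2/lat)
      delta <- (g_i_new + g_n_new + p_new + log(lat2b)) -
        (g[blk] + g_n_old + pv[blk] + log(latent[blk]))
      acc <- is.finite(delta) & log(runif(nb)) < delta
      bat_try_lat[blk] <- bat_try_lat[blk] + 1
      if (!in_burn) try_lat[blk] <- try_lat[blk] + 1
      if (any(acc)) {
        ai <- blk[acc]
        latent[ai] <- lat2b[acc]
        g[ai] <- g_i_new[acc]
        pv[ai] <- p_new[acc]
        if (markov) {
          up <- which(acc & has_nxt)
          if (length(up)) g[nxt[up]] <- g_n_new[up]
        }
        bat_acc_lat[ai] <- bat_acc_lat[ai] + 1
        if (!in_burn) acc_lat[ai] <- acc_lat[ai] + 1
        lp_par <- sum(g) + lp_prior
      }
    }

    ## --- adaptation during burn-in, batches of 50 ---
    if (in_burn && it %% 50L == 0L) {
      for (p in free) {
        rate <- bat_acc_par[[p]] / max(bat_try_par[[p]], 1)
        if (rate > 0.4) steps[[p]] <- steps[[p]] * 1.3
        else if (rate < 0.2) steps[[p]] <- steps[[p]] / 1.3
      }
      rate_l <- bat_acc_lat / pmax(bat_try_lat, 1)
      step_lat <- ifelse(rate_l > 0.4, step_lat * 1.3,
                         ifelse(rate_l < 0.2, step_lat / 1.3, step_lat))
      bat_acc_par[] <- 0; bat_try_par[] <- 0
      bat_acc_lat[] <- 0; bat_try_lat[] <- 0
    }

    ## --- retain ---
    if (!in_burn && (it - n_burn) %% thin == 0L) {
      ki <- ki + 1L
      draws[ki, ] <- par[free]
      if (keep_latent) lat_draws[ki, ] <- latent
    }
  }

  accept <- c(acc_par / pmax(try_par, 1),
              latent = sum(acc_lat) / max(sum(try_lat), 1))
  structure(
    list(draws = draws[seq_len(ki), , drop = FALSE],
         latent_draws = if (keep_latent) lat_draws[seq_len(ki), , drop = FALSE],
         accept = accept,
         settings = list(n_iter = n_iter, n_burn = n_burn, thin = thin,
                         mode = mode, seed = seed),
         priors = priors),
    class = "posterior_sample"
  )
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("Posterior sample: %d draws of (%s), scenario %s\n",
              nrow(x$draws), paste(colnames(x$draws), collapse = ", "),
              x$priors$scenario))
  cat("Acceptance rates:",
      paste(sprintf("%s=%.2f", names(x$accept), x$accept), collapse = ", "),
      "\n")
  invisible(x)
}

# Effective sample size from the empirical autocorrelation, truncated at
# the first negative value (Geyer-style initial positive sequence, simple
# variant).
ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Summaries of the interaction-strength posterior
#'
#' Posterior mean, standard error (the standard deviation of the
#' inferred distribution), the probability mass below and above the
#' bifurcation at `alpha = 1`, a central 95% credible interval, and an
#' effective sample size for `alpha`.
#'
#' @param sample A [mh_sample()] result.
#' @return A list of class `"posterior_summary"` with fields
#'   `mean_alpha`, `se_alpha`, `mass_below_1`, `mass_above_1`, `ci95`,
#'   `ess_alpha`, `accept`.
#' @export
posterior_summary <- function(sample) {
  stopifnot(inherits(sample, "posterior_sample"), nrow(sample$draws) > 0)
  a <- sample$draws[, "alpha"]
  structure(
    list(mean_alpha = mean(a),
         se_alpha = if (length(a) > 1L) sd(a) else 0,
         mass_below_1 = mean(a < 1),
         mass_above_1 = mean(a > 1),
         ci95 = unname(quantile(a, c(0.025, 0.975))),
         ess_alpha = ess(a),
         accept = sample$accept),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("alpha: mean %.3f, SE %.3f, 95%% CI [%.3f, %.3f]\n",
              x$mean_alpha, x$se_alpha, x$ci95[1], x$ci95[2]))
  cat(sprintf("mass below 1: %.3f, above 1: %.3f (ESS %.0f)\n",
              x$mass_below_1, x$mass_above_1, x$ess_alpha))
  invisible(x)
}
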