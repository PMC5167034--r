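#' Exact simulation of the invader birth-death process
#'
#' Samples one trajectory of the one-species stochastic logistic
#' birth-death chain with birth rate \eqn{B(n) = \bar\lambda n (1 - n/N)}
#' and death rate \eqn{D(n) = \mu n}, using the Gillespie algorithm.
#' The resident community's competitive pressure is already absorbed into
#' \eqn{\bar\lambda} (see [effective_params()]); state 0 is absorbing.
#'
#' By default only the population sizes at `times` are stored, which
#' bounds memory at high event rates; set `keep_events = TRUE` to retain
#' the full event list (needed by [sample_at_times()]).
#'
#' @param eff An [effective_params()] object.
#' @param n0 Initial population size (nonnegative integer).
#' @param t_end End of the simulated window (days).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param times Sample times within `[0, t_end]` at which to record the
#'   population size (default: `t_end` only).
#' @param keep_events If `TRUE`, retain every event time and size.
#'
#' @return An object of class `"event_trajectory"`: list with `times`,
#'   `sizes`, `extinct`, `final_size`, `t_end`, and (optionally) `events`
#'   (a list with `times`, `sizes`).
#' @export
#' @examples
#' eff <- effective_params(params_from_delta(1), alpha = 0.5, K_R = 10000)
#' simulate_invader(eff, n0 = 40, t_end = 4, seed = 1, times = c(1, 2, 4))
simulate_invader <- function(eff, n0, t_end, seed = NULL, times = t_end,
                             keep_events = FALSE) {
  stopifnot(inherits(eff, "effective_params"),
            is.numeric(n0), length(n0) == 1L, n0 >= 0, n0 == round(n0),
            is.numeric(t_end), length(t_end) == 1L, t_end > 0)
  times <- sort(as.numeric(times))
  if (any(times < 0) || any(times > t_end)) {
    stop("`times` must lie within [0, t_end]")
  }
  res <- with_seed(seed, .gillespie_invader(eff$lambda_bar, eff$mu, eff$N,
                                            as.integer(n0), t_end, times,
                                            keep_events))
  traj <- list(times = times, sizes = res$sampled, extinct = res$extinct,
               final_size = res$final_size, t_end = t_end, n0 = as.integer(n0),
               species = "invader")
  if (keep_events) {
    traj$events <- list(times = res$event_times, sizes = res$event_sizes)
  }
  structure(traj, class = "event_trajectory")
}

#' Exact simulation of the resident-invader pair
#'
#' In `joint` mode both species follow the coupled two-species
#' birth-death process with invader rates
#' \eqn{B_I = \lambda_I n_I (1 - (n_I + \alpha_{IR} n_R)/N_I)},
#' \eqn{D_I = \mu_I n_I} and the symmetric resident analogue (the
#' resident's stochastic dynamics mirror the invader's form; negative
#' propensities are clipped to 0). In `clamped` mode the resident is held
#' fixed at its carrying capacity and the invader follows the reduced
#' one-species process with the modified birth rate, which is exactly
#' [simulate_invader()] — identical seeds give identical invader paths.
#' The clamped reduction is what the introduction experiments use; the
#' joint mode exists to verify that the resident indeed stays within 1%
#' of its carrying capacity over the observation window.
#'
#' @param setup A [competition_setup()].
#' @param t_end End of the simulated window (days).
#' @param seed Optional integer seed.
#' @param times Sample times within `[0, t_end]`.
#' @param mode `"clamped"` (resident fixed at K_R) or `"joint"`.
#' @param keep_events Retain the full event list.
#'
#' @return An `"event_trajectory"` with invader sizes in `sizes` and,
#'   additionally, `sizes_resident`.
#' @export
simulate_pair <- function(setup, t_end, seed = NULL, times = t_end,
                          mode = c("clamped", "joint"), keep_events = FALSE) {
  stopifnot(inherits(setup, "competition_setup"))
  mode <- match.arg(mode)
  times <- sort(as.numeric(times))
  if (any(times < 0) || any(times > t_end)) {
    stop("`times` must lie within [0, t_end]")
  }
  if (mode == "clamped") {
    eff <- effective_params(setup$invader, setup$alpha_IR, setup$resident$K)
    traj <- simulate_invader(eff, setup$n0_invader, t_end, seed = seed,
                             times = times, keep_events = keep_events)
    traj$sizes_resident <- rep(setup$resident$K, length(times))
    traj$mode <- "clamped"
    return(traj)
  }
  inv <- setup$invader; res <- setup$resident
  out <- with_seed(seed, .gillespie_pair(
    inv$lambda, inv$mu, inv$N, setup$alpha_IR,
    res$lambda, res$mu, res$N, setup$alpha_RI,
    setup$n0_invader, setup$n0_resident, t_end, times, keep_events))
  traj <- list(times = times, sizes = out$sampled_I,
               sizes_resident = out$sampled_R, extinct = out$extinct,
               final_size = out$final_I, t_end = t_end,
               n0 = setup$n0_invader, species = "invader+resident",
               mode = "joint")
  if (keep_events) {
    traj$events <- list(times = out$event_times, sizes = out$event_sizes_I,
                        sizes_resident = out$event_sizes_R)
  }
  structure(traj, class = "event_trajectory")
}

#' @export
print.event_trajectory <- function(x, ...) {
  cat(sprintf("Birth-death trajectory (%s) over [0, %g] days\n",
              x$species, x$t_end))
  cat(sprintf("  sampled at %d times; final size %d%s\n", length(x$times),
              x$final_size, if (x$extinct) " (extinct)" else ""))
  if (!is.null(x$events)) {
    cat(sprintf("  %d events retained\n", length(x$events$times) - 1L))
  }
  invisible(x)
}

#' Look up population sizes at arbitrary times
#'
#' Right-continuous piecewise-constant lookup on a trajectory's retained
#' event list: the value at `t` is the size after the last event at or
#' before `t`. Requires a trajectory simulated with `keep_events = TRUE`.
#'
#' @param traj An `"event_trajectory"` with events retained.
#' @param times Times within `[0, t_end]` of the trajectory.
#' @return Integer vector of population sizes.
#' @export
sample_at_times <- function(traj, times) {
  stopifnot(inherits(traj, "event_trajectory"))
  if (is.null(traj$events)) {
    stop("trajectory was simulated without `keep_events = TRUE`")
  }
  times <- as.numeric(times)
  if (any(times < 0) || any(times > traj$t_end)) {
    stop("requested times outside the simulated window [0, ", traj$t_end, "]")
  }
  idx <- findInterval(times, traj$events$times)
  traj$events$sizes[idx]
}

#' Poisson observation model for partial searches
#'
#' A survey covering a fraction `f` of the habitat records, for a true
#' abundance \eqn{\bar n}, a count drawn from Poisson with mean
#' \eqn{f \bar n}; counts at different times are independent.
#'
#' @param latent Vector of true abundances, >= 0.
#' @param f Search fraction in (0, 1].
#' @param seed Optional integer seed.
#' @return Integer vector of observed counts.
#' @export
#' @examples
#' observe_counts(c(40, 100, 250), f = 0.25, seed = 1)
observe_counts <- function(latent, f, seed = NULL) {
  stopifnot(is.numeric(latent), all(latent >= 0),
            is.numeric(f), length(f) == 1L, f > 0, f <= 1)
  with_seed(seed, rpois(length(latent), f * latent))
}

#' Replicate ensemble of invader trajectories
#'
#' Simulates `n_reps` independent trajectories, each from its own
#' substream seed derived deterministically from `master_seed`, and
#' summarises the ensemble: per-time mean and variance of the population
#' size and the fraction of replicates extinct (size exactly 0).
#'
#' @param x An [effective_params()] (clamped-resident simulation) or a
#'   [competition_setup()] (`mode` selects clamped or joint simulation).
#' @param n0 Initial invader size; taken from the setup if `x` is one.
#' @param times Sample times (days).
#' @param n_reps Number of replicates, >= 1.
#' @param master_seed Integer master seed.
#' @param mode For a `competition_setup`: `"clamped"` or `"joint"`.
#'
#' @return An object of class `"ensemble_summary"`: a data.frame with
#'   columns `time`, `mean`, `var`, `extinct_frac` (plus `mean_resident`
#'   in joint mode); attributes `n_reps`, `master_seed`.
#' @export
#' @examples
#' eff <- effective_params(params_from_delta(1), alpha = 0.5, K_R = 10000)
#' simulate_ensemble(eff, n0 = 40, times = c(1, 2, 4), n_reps = 200,
#'                   master_seed = 7)
simulate_ensemble <- function(x, n0 = NULL, times, n_reps, master_seed,
                              mode = c("clamped", "joint")) {
  stopifnot(is.numeric(n_reps), n_reps >= 1)
  mode <- match.arg(mode)
  times <- sort(as.numeric(times))
  t_end <- max(times)
  n_reps <- as.integer(n_reps)
  ns <- length(times)
  sizes <- matrix(0, nrow = n_reps, ncol = ns)
  resid <- NULL
  if (inherits(x, "effective_params")) {
    stopifnot(!is.null(n0))
    for (i in seq_len(n_reps)) {
      s <- substream_seed(master_seed, i, "simulate")
      tr <- simulate_invader(x, n0, t_end, seed = s, times = times)
      sizes[i, ] <- tr$sizes
    }
  } else if (inherits(x, "competition_setup")) {
    if (mode == "joint") resid <- matrix(0, nrow = n_reps, ncol = ns)
    for (i in seq_len(n_reps)) {
      s <- substream_seed(master_seed, i, "simulate")
      tr <- simulate_pair(x, t_end, seed = s, times = times, mode = mode)
      sizes[i, ] <- tr$sizes
      if (mode == "joint") resid[i, ] <- tr$sizes_resident
    }
  } else {
    stop("`x` must be an effective_params or competition_setup object")
  }
  out <- data.frame(
    time = times,
    mean = colMeans(sizes),
    var = apply(sizes, 2, function(v) if (n_reps > 1) stats::var(v) else 0),
    extinct_frac = colMeans(sizes == 0)
  )
  if (!is.null(resid)) out$mean_resident <- colMeans(resid)
  structure(out, class = c("ensemble_summary", "data.frame"),
            n_reps = n_reps, master_seed = master_seed)
}
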