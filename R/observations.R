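#' Observation series for an introduction experiment
#'
#' A discretely sampled, imperfectly observed abundance time series: the
#' introduction size `n0` at time 0 (known exactly — it is the controlled
#' number of released individuals), followed by `d` survey counts, each a
#' Poisson thinning (search fraction `f`) of the latent true abundance.
#'
#' @param times Strictly increasing observation times (days), first
#'   element 0.
#' @param counts Observed counts at `times` (nonnegative integers); the
#'   first equals `n0`.
#' @param f Search fraction in (0, 1].
#' @param latent Optional latent true abundances (known for synthetic
#'   data, `NA` for field data).
#'
#' @return An object of class `"observation_series"`.
#' @export
observation_series <- function(times, counts, f, latent = NULL) {
  stopifnot(is.numeric(times), is.numeric(counts),
            length(times) == length(counts), length(times) >= 2L)
  if (times[1] != 0) stop("first observation time must be 0 (introduction)")
  if (any(diff(times) <= 0)) stop("observation times must be strictly increasing")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("observed counts must be nonnegative integers")
  }
  stopifnot(is.numeric(f), length(f) == 1L, f > 0, f <= 1)
  if (!is.null(latent)) {
    stopifnot(length(latent) == length(times), all(is.na(latent) | latent >= 0))
  }
  structure(
    list(times = as.numeric(times), counts = as.integer(counts),
         f = f, latent = latent, n0 = as.integer(counts[1]),
         d = length(times) - 1L),
    class = "observation_series"
  )
}

#' @export
print.observation_series <- function(x, ...) {
  cat(sprintf(
    "Observation series: n0 = %d, d = %d surveys over (0, %g] days, f = %g\n",
    x$n0, x$d, max(x$times), x$f))
  df <- data.frame(time = x$times, observed = x$counts)
  if (!is.null(x$latent)) df$latent <- x$latent
  print(df, row.names = FALSE)
  invisible(x)
}

#' Default survey schedule
#'
#' `d` equally spaced observation times in `(0, t_max]`: with the
#' defaults, surveys twice a day for the first 4 days (t = 0.4, 0.8, ...,
#' 4.0), i.e. on average twice per invader generation at r = 1/day.
#'
#' @param d Number of surveys after the introduction.
#' @param t_max Last survey time (days).
#' @return Numeric vector of length `d`.
#' @export
observation_times <- function(d = 10, t_max = 4) {
  stopifnot(d >= 1, t_max > 0)
  seq_len(d) * (t_max / d)
}

#' Simulate a complete synthetic introduction data set
#'
#' Runs the clamped-resident Gillespie simulation at the given
#' interaction strength and noise level, samples the latent abundance on
#' the survey schedule and applies the Poisson observation model. This is
#' the generator behind all inference experiments: `delta` fixes
#' (\eqn{\lambda, \mu, N}) through the noise parameterization, the
#' resident sits at `K_R`, and the invader starts from `n0` individuals.
#'
#' @param alpha Interaction strength (resident on invader).
#' @param delta Demographic noise coefficient (day^-1).
#' @param n0 Introduction size (default 40 individuals).
#' @param d Number of surveys (default 10).
#' @param t_max Length of the observation window (default 4 days).
#' @param f Search fraction (default 0.25).
#' @param K_R Resident carrying capacity (default 10000).
#' @param seed Optional integer seed (drives both the demographic and the
#'   observation randomness through named substreams).
#'
#' @return An [observation_series()] with the latent path attached.
#' @export
#' @examples
#' simulate_observation_series(alpha = 0.8, delta = 1.75, seed = 1)
simulate_observation_series <- function(alpha, delta, n0 = 40, d = 10,
                                        t_max = 4, f = 0.25, K_R = 10000,
                                        seed = NULL) {
  inv <- params_from_delta(delta)
  eff <- effective_params(inv, alpha, K_R)
  tt <- observation_times(d, t_max)
  sim_seed <- if (is.null(seed)) NULL else substream_seed(seed, 0L, "simulate")
  obs_seed <- if (is.null(seed)) NULL else substream_seed(seed, 0L, "observe")
  traj <- simulate_invader(eff, n0, t_end = t_max, seed = sim_seed, times = tt)
  counts <- observe_counts(traj$sizes, f, seed = obs_seed)
  observation_series(times = c(0, tt), counts = c(n0, counts), f = f,
                     latent = c(n0, traj$sizes))
}

#' Write / read an observation series as CSV
#'
#' Plain long-format CSV with header `time,observed_count` (plus
#' `latent_count` when the latent path is known); the search fraction and
#' introduction size travel in a JSON sidecar `<path>.meta.json` so the
#' round trip is lossless.
#'
#' @param series An [observation_series()].
#' @param path CSV file path.
#' @export
write_observations <- function(series, path) {
  stopifnot(inherits(series, "observation_series"))
  df <- data.frame(time = format(series$times, digits = 10, trim = TRUE),
                   observed_count = series$counts)
  if (!is.null(series$latent)) {
    df$latent_count <- format(series$latent, digits = 10, trim = TRUE)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(f = series$f, n0 = series$n0, d = series$d),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_observations
#' @param f Search fraction; only needed if the sidecar file is missing.
#' @export
read_observations <- function(path, f = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "observed_count") %in% names(df))) {
    stop("malformed observation CSV: need columns time, observed_count")
  }
  bad <- which(!is.finite(df$time) | !is.finite(df$observed_count))
  if (length(bad)) {
    stop("malformed observation CSV at data row(s) ",
         paste(bad, collapse = ", "))
  }
  if (any(diff(df$time) <= 0)) {
    stop("observation times must be strictly increasing")
  }
  meta_path <- paste0(path, ".meta.json")
  if (is.null(f)) {
    if (!file.exists(meta_path)) {
      stop("no sidecar ", meta_path, " found; pass `f` explicitly")
    }
    f <- jsonlite::read_json(meta_path)$f
  }
  latent <- if ("latent_count" %in% names(df)) df$latent_count else NULL
  observation_series(times = df$time, counts = df$observed_count,
                     f = f, latent = latent)
}
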