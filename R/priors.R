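#' Prior specification for the four knowledge scenarios
#'
#' Establishment inference is studied under graded prior knowledge of the
#' invader's single-species parameters (`r`, `K`, `N`):
#' \describe{
#'   \item{`ALL_FIXED`}{all single-species parameters fixed to their true
#'     values; only `alpha` is free (perfect-knowledge benchmark).}
#'   \item{`PRIOR_K`}{lognormal prior on the carrying capacity `K` only.}
#'   \item{`PRIOR_K_N`}{lognormal priors on `K` and `N`.}
#'   \item{`PRIOR_K_N_R`}{lognormal priors on `K`, `N` and `r`.}
#' }
#' All lognormal priors share one width parameter `sigma` (log-scale
#' standard deviation) and have their median anchored at the true value.
#' The interaction strength `alpha` always carries a flat prior on
#' `alpha_support` (default `[0, 2]`, the interaction range over which
#' the deterministic model exhibits all its outcomes), which makes the
#' flat prior proper. The resident carrying capacity `K_R` is always
#' fixed.
#'
#' @param scenario One of `"ALL_FIXED"`, `"PRIOR_K"`, `"PRIOR_K_N"`,
#'   `"PRIOR_K_N_R"`.
#' @param sigma Prior width (log-scale SD), in `[0.01, 1]`. Ignored for
#'   `ALL_FIXED`.
#' @param anchors Named list with true values `r`, `K`, `N`, `K_R`
#'   (see [anchors_from_delta()]).
#' @param alpha_support Numeric length-2 support of the flat alpha prior.
#'
#' @return An object of class `"prior_spec"`.
#' @export
#' @examples
#' build_priors("PRIOR_K", sigma = 0.3, anchors = anchors_from_delta(1.75))
build_priors <- function(scenario, sigma = 0.3, anchors,
                         alpha_support = c(0, 2)) {
  scenarios <- list(
    ALL_FIXED = character(0),
    PRIOR_K = "K",
    PRIOR_K_N = c("K", "N"),
    PRIOR_K_N_R = c("K", "N", "r")
  )
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% names(scenarios)) {
    stop("unknown scenario: ", paste(scenario, collapse = ", "),
         " (expected one of ", paste(names(scenarios), collapse = ", "), ")")
  }
  if (scenario != "ALL_FIXED") {
    stopifnot(is.numeric(sigma), length(sigma) == 1L,
              sigma >= 0.01, sigma <= 1)
  }
  stopifnot(is.list(anchors), all(c("r", "K", "N", "K_R") %in% names(anchors)),
            length(alpha_support) == 2L, alpha_support[1] < alpha_support[2],
            alpha_support[1] >= 0)
  structure(
    list(scenario = scenario, sigma = sigma, anchors = anchors,
         with_prior = scenarios[[scenario]],
         free = c("alpha", scenarios[[scenario]]),
         alpha_support = as.numeric(alpha_support)),
    class = "prior_spec"
  )
}

#' True-parameter anchors from the noise parameterization
#'
#' Convenience wrapper building the anchor list (`r`, `K`, `N`, `K_R`)
#' that [build_priors()] expects from the delta parameterization, with
#' the resident fixed at its carrying capacity.
#'
#' @param delta Demographic noise coefficient.
#' @param K_R Resident carrying capacity (default 10000).
#' @return Named list `r`, `K`, `N`, `K_R`.
#' @export
anchors_from_delta <- function(delta, K_R = 10000) {
  p <- params_from_delta(delta)
  list(r = p$r, K = p$K, N = p$N, K_R = K_R)
}

#' Log prior density
#'
#' Sum of the lognormal log-densities (natural scale) of the parameters
#' under a prior, plus the flat alpha prior (`-Inf` outside its support,
#' a constant inside). Parameters without a prior are fixed and
#' contribute nothing.
#'
#' @param theta Named list/vector with at least `alpha` and any
#'   parameters carrying priors (natural scale).
#' @param priors A [build_priors()] object.
#' @return Scalar log prior density (unnormalized for alpha).
#' @export
log_prior <- function(theta, priors) {
  stopifnot(inherits(priors, "prior_spec"))
  a <- theta[["alpha"]]
  if (a < priors$alpha_support[1] || a > priors$alpha_support[2]) return(-Inf)
  lp <- 0
  for (p in priors$with_prior) {
    lp <- lp + stats::dlnorm(theta[[p]], meanlog = log(priors$anchors[[p]]),
                             sdlog = priors$sigma, log = TRUE)
  }
  lp
}

#' Unnormalized log posterior over parameters and latent abundances
#'
#' Composite log-likelihood plus log prior; the marginal likelihood is
#' set to one throughout (only posterior ratios matter for
#' Metropolis-Hastings). The latent abundances carry flat (uniform)
#' priors on their admissible positive range.
#'
#' @param theta Named list with natural-scale `r`, `K`, `N`, `alpha`
#'   (free or fixed values; fixed ones from the anchors).
#' @param latent Latent abundances at the survey times.
#' @param obs An [observation_series()].
#' @param priors A [build_priors()] object.
#' @param mode Conditioning convention, see [loglikelihood()].
#' @return Scalar unnormalized log posterior.
#' @export
log_posterior <- function(theta, latent, obs, priors,
                          mode = c("markov", "origin")) {
  lp <- log_prior(theta, priors)
  if (!is.finite(lp)) return(-Inf)
  if (theta[["N"]] < theta[["K"]]) return(-Inf)  # negative death rate
  ip <- inference_params(r = theta[["r"]], K = theta[["K"]], N = theta[["N"]],
                         K_R = priors$anchors$K_R, alpha = theta[["alpha"]])
  lp + loglikelihood(obs, latent, ip, mode = match.arg(mode))
}
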