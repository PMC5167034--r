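#' @useDynLib establishr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm dpois rpois runif rnorm quantile sd acf optimize
#' @importFrom utils write.csv read.csv
NULL

.M31 <- 2147483647  # 2^31 - 1; all seed arithmetic stays below 2^53 in doubles

#' Derive a reproducible substream seed
#'
#' Deterministically hashes a master seed, a replicate index and an
#' optional stream label into an integer seed for [set.seed()]. Used
#' throughout so that every replicate of every stage of an experiment is
#' individually re-runnable from the master seed.
#'
#' @param master Integer master seed.
#' @param index Replicate index (nonnegative integer).
#' @param stream Optional character label naming the stage
#'   (e.g. `"simulate"`, `"observe"`, `"mcmc"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, index = 0L, stream = "") {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(index), length(index) == 1L, index >= 0)
  h <- 0
  if (nzchar(stream)) {
    for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% .M31
  }
  s <- ((abs(master) %% .M31) * 1103515245 + 12345) %% .M31
  s <- (s + h * 2654435) %% .M31
  s <- (s + index * 1013904223) %% .M31
  s <- (s * 48271) %% .M31
  as.integer(s)
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. With seed = NULL the current RNG stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
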