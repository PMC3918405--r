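# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so package functions never
#' clobber the user's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialise a stream to save
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero (R's round() is banker's rounding).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Target subset size for a sampling percentage
#'
#' Applies the round-half-away-from-zero rule to `n * percentage / 100`.
#' Percentages that would yield fewer than 2 accessions are an error: the
#' evaluation statistics (variance, CV, range) are undefined below 2.
#'
#' @param n number of accessions in the initial collection.
#' @param percentage sampling percentage in (0, 100].
#' @return integer target size.
#' @examples
#' target_size(168, 6.07) # 10
#' @export
target_size <- function(n, percentage) {
  stopifnot(is.numeric(n), n >= 2, is.numeric(percentage))
  if (percentage <= 0 || percentage > 100) {
    stop("`percentage` must be in (0, 100], got ", percentage)
  }
  k <- as.integer(round_half_up(n * percentage / 100))
  if (k < 2L) {
    stop("sampling percentage ", percentage, "% of ", n,
         " accessions yields ", k, " (< 2) accessions")
  }
  k
}

`%||%` <- function(a, b) if (is.null(a)) b else a
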