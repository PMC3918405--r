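# Least Distance Stepwise Sampling (LDSS) and the completely-random
# control sampler (CK).
#
# LDSS repeatedly locates the globally closest pair of remaining
# accessions (the least-distance subgroup, identical to the first UPGMA
# merge), keeps one member uniformly at random and removes the other,
# until the target subset size is reached. Distances are computed once on
# the standardized initial collection (fixed reference) so each deletion
# is a submatrix operation; an optional re-estimation policy recomputes
# distances from the surviving accessions after every removal.

#' Construct a subcore collection by least distance stepwise sampling
#'
#' @param matrix a [trait_matrix()] of genotypic values (unstandardized;
#'   standardization to the initial collection happens internally).
#' @param percentage sampling percentage in (0, 100]; the target size is
#'   `round_half_up(N * percentage / 100)` and must be >= 2.
#' @param metric genetic distance, see [trait_distance()].
#' @param seed RNG seed driving the keep-vs-remove coin flips.
#' @param reference_policy `"fixed"` (default): standardization and
#'   covariance parameters estimated once on the initial collection;
#'   `"refit"`: re-estimated from the survivors after every removal.
#' @param snapshot_percentages optional vector of additional percentages
#'   (all >= `percentage`); the subsets passed through at those sizes are
#'   recorded, exploiting that the removal stream does not depend on the
#'   stopping size.
#' @return list of class `subcore_result`: `selected` ids,
#'   `sampling_percentage`, `metric`, `seed`, `trace` (data.frame removed,
#'   kept, distance in removal order), `method = "ldss"`, and `snapshots`
#'   (named list of id vectors) when requested.
#' @export
ldss_sample <- function(matrix, percentage, metric = "seuclid", seed = NULL,
                        reference_policy = c("fixed", "refit"),
                        snapshot_percentages = NULL) {
  reference_policy <- match.arg(reference_policy)
  n <- nrow(matrix)
  ids <- accessions(matrix)
  k_target <- target_size(n, percentage)
  snap_sizes <- integer(0)
  if (!is.null(snapshot_percentages)) {
    snap_sizes <- vapply(snapshot_percentages, function(p) target_size(n, p), 1L)
    if (any(snap_sizes < k_target)) {
      stop("snapshot percentages must not fall below the target percentage")
    }
  }

  z <- standardize(matrix)
  D <- as.matrix(trait_distance(z, metric))
  diag(D) <- Inf
  active <- rep(TRUE, n)
  trace <- list()
  snapshots <- stats::setNames(vector("list", length(snap_sizes)),
                               as.character(snapshot_percentages))

  with_seed(seed, {
    n_active <- n
    while (n_active > k_target) {
      hit <- which(snap_sizes == n_active)
      for (s in hit) snapshots[[s]] <- ids[active]
      if (reference_policy == "refit" && n_active < n) {
        D <- matrix(Inf, n, n)
        sub <- trait_matrix(unclass(matrix)[active, , drop = FALSE])
        Dsub <- as.matrix(trait_distance(standardize(sub), metric))
        diag(Dsub) <- Inf
        D[active, active] <- Dsub
      }
      flat <- which.min(D)              # column-major: lexicographic (i, j)
      j <- ((flat - 1L) %/% n) + 1L     # pair {i, j}, i = min index
      i <- ((flat - 1L) %% n) + 1L
      pair <- sort(c(i, j))
      keep_first <- stats::runif(1L) < 0.5
      kept <- if (keep_first) pair[1L] else pair[2L]
      removed <- if (keep_first) pair[2L] else pair[1L]
      trace[[length(trace) + 1L]] <- data.frame(
        removed = ids[removed], kept = ids[kept],
        distance = D[pair[1L], pair[2L]], stringsAsFactors = FALSE)
      D[removed, ] <- Inf
      D[, removed] <- Inf
      active[removed] <- FALSE
      n_active <- n_active - 1L
    }
    hit <- which(snap_sizes == n_active)
    for (s in hit) snapshots[[s]] <- ids[active]
  })

  structure(list(
    selected = ids[active],
    sampling_percentage = percentage,
    metric = metric, seed = seed, method = "ldss",
    reference_policy = reference_policy,
    trace = if (length(trace)) do.call(rbind, trace)
            else data.frame(removed = character(0), kept = character(0),
                            distance = numeric(0)),
    snapshots = if (length(snap_sizes)) snapshots else NULL),
    class = "subcore_result")
}

#' Completely random control subset (CK)
#'
#' Uniform sampling without replacement to the same target-size rule as
#' [ldss_sample()].
#'
#' @inheritParams ldss_sample
#' @return list of class `subcore_result` with `method = "random"`.
#' @export
random_sample <- function(matrix, percentage, seed = NULL) {
  n <- nrow(matrix)
  ids <- accessions(matrix)
  k_target <- target_size(n, percentage)
  sel <- with_seed(seed, sort(sample.int(n, k_target)))
  structure(list(
    selected = ids[sel], sampling_percentage = percentage,
    metric = NA_character_, seed = seed, method = "random",
    trace = data.frame(removed = character(0), kept = character(0),
                       distance = numeric(0))),
    class = "subcore_result")
}

#' @export
print.subcore_result <- function(x, ...) {
  cat(sprintf("<subcore_result> %s: %d accessions selected at %.2f%%%s\n",
              x$method, length(x$selected), x$sampling_percentage,
              if (!is.na(x$metric)) paste0(" (", x$metric, ")") else ""))
  invisible(x)
}
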