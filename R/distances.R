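# Trait standardization, the six genetic distances, and UPGMA clustering.
#
# Distances are returned as a stats::dist object (condensed, with accession
# ids as Labels) so they plug directly into hclust and into the stepwise
# sampler. For seuclid and mahal the scaling parameters (per-trait sd,
# covariance) come from a *reference* collection — by default the matrix
# itself — and are held fixed while accessions are deleted, which makes
# deletion a pure submatrix operation on the distances.

SUPPORTED_METRICS <- c("euclid", "seuclid", "mahal", "cityblock",
                       "cosine", "correlation")

#' Per-trait standardization parameters
#'
#' @param matrix a [trait_matrix()] used as the reference collection.
#' @return list of class `standardization_params` with per-trait `mean` and
#'   sample (`n - 1`) `sd`.
#' @export
standardization_params <- function(matrix) {
  mu <- colMeans(matrix)
  sd <- apply(matrix, 2L, stats::sd)
  zero <- sd <= 0
  if (any(zero)) {
    stop("zero-variance trait(s): ", paste(traits(matrix)[zero], collapse = ", "),
         "; cannot standardize")
  }
  structure(list(mean = mu, sd = sd, traits = traits(matrix)),
            class = "standardization_params")
}

#' Standardize a trait matrix to z-scores
#'
#' @param matrix a [trait_matrix()].
#' @param params reference [standardization_params()]; defaults to the
#'   matrix's own.
#' @return a [trait_matrix()] of z-scores.
#' @export
standardize <- function(matrix, params = standardization_params(matrix)) {
  if (!identical(params$traits, traits(matrix))) {
    stop("standardization params cover traits ",
         paste(params$traits, collapse = ","), " but matrix has ",
         paste(traits(matrix), collapse = ","))
  }
  z <- sweep(sweep(unclass(matrix), 2L, params$mean, `-`), 2L, params$sd, `/`)
  trait_matrix(z, accessions(matrix), traits(matrix))
}

#' Pairwise genetic distances between accessions
#'
#' Six metrics: `euclid` (Euclidean), `seuclid` (Euclidean on z-scores
#' w.r.t. the reference), `mahal` (Mahalanobis with the reference
#' covariance), `cityblock` (Manhattan), `cosine` (1 - cosine similarity),
#' `correlation` (1 - Pearson correlation between trait vectors).
#'
#' @param matrix a [trait_matrix()].
#' @param metric one of `"euclid"`, `"seuclid"`, `"mahal"`, `"cityblock"`,
#'   `"cosine"`, `"correlation"`.
#' @param reference reference [trait_matrix()] for seuclid/mahal scaling
#'   parameters; defaults to `matrix` itself.
#' @return a `stats::dist` object with accession ids as labels. For
#'   `mahal` with singular reference covariance, the Moore-Penrose
#'   pseudo-inverse is used and attribute `pseudo_inverse` is set.
#' @export
trait_distance <- function(matrix, metric = SUPPORTED_METRICS,
                           reference = NULL) {
  metric <- match.arg(metric)
  reference <- reference %||% matrix
  x <- unclass(matrix)
  pseudo <- FALSE
  d <- switch(metric,
    euclid = stats::dist(x, method = "euclidean"),
    cityblock = stats::dist(x, method = "manhattan"),
    seuclid = stats::dist(unclass(standardize(matrix,
                                              standardization_params(reference))),
                          method = "euclidean"),
    mahal = {
      if (ncol(x) < 2L) stop("mahal requires at least 2 traits")
      S <- stats::cov(unclass(reference))
      W <- tryCatch(chol(solve(S)), error = function(e) NULL)
      if (is.null(W)) {
        pseudo <- TRUE
        P <- MASS::ginv(S)
        E <- eigen(P, symmetric = TRUE)
        keep <- E$values > max(E$values) * 1e-12
        W <- diag(sqrt(E$values[keep]), sum(keep)) %*% t(E$vectors[, keep, drop = FALSE])
      }
      stats::dist(x %*% t(W), method = "euclidean")
    },
    cosine = {
      nrm <- sqrt(rowSums(x^2))
      if (any(nrm == 0)) {
        stop("cosine distance undefined for zero-norm accession(s): ",
             paste(accessions(matrix)[nrm == 0], collapse = ", "))
      }
      sim <- tcrossprod(x / nrm)
      stats::as.dist(pmax(1 - sim, 0))
    },
    correlation = {
      if (ncol(x) < 2L) stop("correlation distance requires at least 2 traits")
      xc <- x - rowMeans(x)
      nrm <- sqrt(rowSums(xc^2))
      if (any(nrm == 0)) {
        stop("correlation distance undefined for zero-variance accession(s): ",
             paste(accessions(matrix)[nrm == 0], collapse = ", "))
      }
      sim <- tcrossprod(xc / nrm)
      stats::as.dist(pmax(1 - sim, 0))
    })
  attr(d, "Labels") <- accessions(matrix)
  attr(d, "metric") <- metric
  if (pseudo) attr(d, "pseudo_inverse") <- TRUE
  d
}

#' UPGMA (average linkage) clustering
#'
#' Classic unweighted pair-group agglomeration: at each step the two
#' clusters with the smallest average inter-cluster distance are merged,
#' the first merge joining the globally closest accession pair.
#'
#' @param d a `stats::dist` object (e.g. from [trait_distance()]).
#' @return list of class `upgma_tree`: `merges` (list of
#'   `(members_a, members_b, height)` in merge order), `heights`, `labels`,
#'   and the underlying `hclust` object.
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) stop("`d` must be a stats::dist object")
  hc <- stats::hclust(d, method = "average")
  labels <- hc$labels %||% as.character(seq_len(attr(d, "Size")))
  members <- function(k) {
    if (k < 0) labels[-k] else unlist(lapply(hc$merge[k, ], members))
  }
  merges <- lapply(seq_len(nrow(hc$merge)), function(i) {
    list(members_a = sort(members(hc$merge[i, 1L])),
         members_b = sort(members(hc$merge[i, 2L])),
         height = hc$height[i])
  })
  structure(list(merges = merges, heights = hc$height, labels = labels,
                 hclust = hc),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, %d merges, heights [%.4g, %.4g]\n",
              length(x$labels), length(x$heights),
              min(x$heights), max(x$heights)))
  invisible(x)
}
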