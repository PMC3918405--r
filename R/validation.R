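# Validation of the optimal sampling percentage: LDSS subcores (treat)
# versus completely random controls (CK) on the ratio statistics, and a
# principal-component projection of core vs reserve accessions.

#' Compare LDSS subcores against random controls
#'
#' For each sampling percentage and seed, builds one LDSS subset (treat)
#' and one random subset (CK) and evaluates the five ratio statistics;
#' reports per-(percentage, method) means and standard deviations across
#' seeds, plus the per-seed detail.
#'
#' @param matrix a [trait_matrix()].
#' @param percentages sampling percentages.
#' @param seeds integer vector of seeds (one pair of subsets per seed).
#' @param metric genetic distance for LDSS.
#' @param alpha significance level for the evaluation tests.
#' @return list of class `treat_ck_comparison`: `summary` data.frame
#'   (percentage, method, then mean/sd per statistic) and `detail`.
#' @export
compare_treat_ck <- function(matrix, percentages = c(6.07, 10, 15),
                             seeds = 1:20, metric = "seuclid",
                             alpha = 0.05) {
  stats_ <- c("CR", "VR", "CR_max", "CR_min", "CR_mea")
  rows <- list()
  for (p in percentages) {
    for (s in seeds) {
      treat <- ldss_sample(matrix, p, metric = metric, seed = s)
      ck <- random_sample(matrix, p, seed = s)
      for (sub in list(treat, ck)) {
        ev <- evaluate_core(matrix, sub$selected, alpha = alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          percentage = p, method = if (sub$method == "ldss") "treat" else "CK",
          seed = s, t(unlist(ev[stats_])), stringsAsFactors = FALSE)
      }
    }
  }
  detail <- do.call(rbind, rows)
  agg_mean <- stats::aggregate(detail[stats_],
                               by = detail[c("percentage", "method")], mean)
  agg_sd <- stats::aggregate(detail[stats_],
                             by = detail[c("percentage", "method")], stats::sd)
  names(agg_sd)[-(1:2)] <- paste0(stats_, "_sd")
  summary <- merge(agg_mean, agg_sd, by = c("percentage", "method"))
  summary <- summary[order(summary$percentage, summary$method == "CK"), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, detail = detail,
                 metric = metric, seeds = seeds),
            class = "treat_ck_comparison")
}

#' @export
print.treat_ck_comparison <- function(x, digits = 2, ...) {
  cat(sprintf("<treat_ck_comparison> %s, %d seeds\n", x$metric,
              length(x$seeds)))
  s <- x$summary
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], round, digits)
  print(s)
  invisible(x)
}

#' Project accessions onto the first two principal components
#'
#' PCA on the correlation scale (column-standardized traits, sensible for
#' heterogeneous units). All accessions are projected; core members are
#' flagged. Component signs are fixed by making each loading vector's
#' largest-magnitude entry positive, so the projection is deterministic.
#'
#' @param matrix a [trait_matrix()] with at least 3 accessions and 2
#'   traits.
#' @param core_ids accession ids forming the core.
#' @return list of class `pca_projection`: `scores` data.frame
#'   (accession, pc1, pc2, role core/reserve), `explained` (percent
#'   variance of PC1 and PC2), `explained_total` (their sum), `loadings`.
#' @export
project_pca <- function(matrix, core_ids) {
  if (nrow(matrix) < 3L) stop("PCA projection needs at least 3 accessions")
  if (ncol(matrix) < 2L) stop("PCA projection needs at least 2 traits")
  core_ids <- check_core_ids(matrix, core_ids)
  pc <- stats::prcomp(unclass(matrix), center = TRUE, scale. = TRUE)
  if (sum(pc$sdev > 1e-10) < 2L) {
    stop("trait matrix has rank < 2; no plane to project onto")
  }
  # deterministic sign convention
  for (j in 1:2) {
    piv <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[piv, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  varfrac <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(
    accession = accessions(matrix),
    pc1 = pc$x[, 1L], pc2 = pc$x[, 2L],
    role = ifelse(accessions(matrix) %in% core_ids, "core", "reserve"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(scores = scores,
                 explained = varfrac[1:2],
                 explained_total = sum(varfrac[1:2]),
                 all_explained = varfrac,
                 loadings = pc$rotation[, 1:2]),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("<pca_projection> PC1+PC2 explain %.2f%% (%.2f + %.2f); %d core, %d reserve\n",
              x$explained_total, x$explained[1], x$explained[2],
              sum(x$scores$role == "core"), sum(x$scores$role == "reserve")))
  invisible(x)
}
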