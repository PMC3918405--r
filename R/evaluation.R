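# The seven evaluation statistics comparing a (sub)core collection with
# its initial collection, computed on UNstandardized trait values:
#
#   MD     = 100 * S_t / n   (traits with significant mean difference)
#   VD     = 100 * S_F / n   (traits with significant variance difference)
#   CR     = mean_i 100 * range_core(i)  / range_init(i)
#   VR     = mean_i 100 * CV_core(i)     / CV_init(i)
#   CR_max = mean_i 100 * max_core(i)    / max_init(i)
#   CR_min = mean_i 100 * min_init(i)    / min_core(i)   (inverted ratio)
#   CR_mea = mean_i 100 * mean_core(i)   / mean_init(i)
#
# MD uses a pooled-variance two-sample t-test, VD a two-sided
# variance-ratio F-test, both at `alpha`. Ratio terms whose denominator is
# zero, or whose numerator and denominator differ in sign, are excluded
# from that statistic's average and reported.

EVALUATION_PARAMETERS <- c("MD", "VD", "CR", "VR", "CR_max", "CR_min", "CR_mea")

#' Evaluate a core subset against its initial collection
#'
#' @param initial a [trait_matrix()] for the full initial collection
#'   (unstandardized genotypic values).
#' @param core_ids accession ids of the core subset (must be a subset of
#'   the initial collection, size >= 2).
#' @param alpha significance level for the mean (t) and variance (F)
#'   tests.
#' @return list of class `evaluation_report` with the seven statistics (in
#'   percent), `S_t`, `S_F`, `n_traits`, `alpha`, a per-trait `detail`
#'   data.frame, and `excluded` (per-statistic list of traits excluded
#'   from the ratio average, with reasons).
#' @export
evaluate_core <- function(initial, core_ids, alpha = 0.05) {
  core_ids <- check_core_ids(initial, core_ids)
  if (ncol(initial) < 1L) stop("no traits to evaluate")
  core <- unclass(initial)[core_ids, , drop = FALSE]
  full <- unclass(initial)
  nt <- ncol(full)

  detail <- data.frame(
    trait = traits(initial),
    mean_init = colMeans(full), mean_core = colMeans(core),
    var_init = apply(full, 2L, stats::var),
    var_core = apply(core, 2L, stats::var),
    min_init = apply(full, 2L, min), min_core = apply(core, 2L, min),
    max_init = apply(full, 2L, max), max_core = apply(core, 2L, max),
    row.names = NULL, stringsAsFactors = FALSE)
  detail$range_init <- detail$max_init - detail$min_init
  detail$range_core <- detail$max_core - detail$min_core
  detail$cv_init <- ifelse(detail$mean_init != 0,
                           sqrt(detail$var_init) / detail$mean_init, NA_real_)
  detail$cv_core <- ifelse(detail$mean_core != 0,
                           sqrt(detail$var_core) / detail$mean_core, NA_real_)

  detail$p_mean <- vapply(seq_len(nt), function(i) {
    pooled_t_pvalue(core[, i], full[, i])
  }, numeric(1))
  detail$p_var <- vapply(seq_len(nt), function(i) {
    variance_f_pvalue(core[, i], full[, i])
  }, numeric(1))
  S_t <- sum(detail$p_mean < alpha, na.rm = TRUE)
  S_F <- sum(detail$p_var < alpha, na.rm = TRUE)

  excluded <- list()
  ratio_stat <- function(name, num, den, sign_sensitive = TRUE) {
    bad_zero <- den == 0
    bad_sign <- if (sign_sensitive) num * den < 0 else rep(FALSE, nt)
    bad_na <- is.na(num) | is.na(den)
    bad <- bad_zero | bad_sign | bad_na
    if (any(bad)) {
      excluded[[name]] <<- data.frame(
        trait = detail$trait[bad],
        reason = ifelse(bad_na[bad], "undefined term",
                 ifelse(bad_zero[bad], "zero denominator", "sign-crossing ratio")),
        stringsAsFactors = FALSE)
    }
    if (all(bad)) return(NA_real_)
    mean(100 * num[!bad] / den[!bad])
  }

  out <- list(
    MD = 100 * S_t / nt,
    VD = 100 * S_F / nt,
    CR = ratio_stat("CR", detail$range_core, detail$range_init,
                    sign_sensitive = FALSE),
    VR = ratio_stat("VR", detail$cv_core, detail$cv_init),
    CR_max = ratio_stat("CR_max", detail$max_core, detail$max_init),
    CR_min = ratio_stat("CR_min", detail$min_init, detail$min_core),
    CR_mea = ratio_stat("CR_mea", detail$mean_core, detail$mean_init),
    S_t = S_t, S_F = S_F, n_traits = nt, alpha = alpha,
    n_core = length(core_ids), n_initial = nrow(initial),
    detail = detail, excluded = excluded)
  class(out) <- "evaluation_report"
  out
}

# Pooled-variance two-sample t-test p-value; identical samples give p = 1.
pooled_t_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  if (se == 0) return(if (mean(x) == mean(y)) 1 else 0)
  2 * stats::pt(-abs((mean(x) - mean(y)) / se), df)
}

# Two-sided variance-ratio F-test p-value.
variance_f_pvalue <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) return(1)
  if (vx == 0 || vy == 0) return(0)
  f <- vx / vy
  p <- stats::pf(f, length(x) - 1L, length(y) - 1L)
  2 * min(p, 1 - p)
}

#' Extract one evaluation statistic by name
#'
#' @param report an `evaluation_report`.
#' @param parameter one of `"MD"`, `"VD"`, `"CR"`, `"VR"`, `"CR_max"`,
#'   `"CR_min"`, `"CR_mea"`.
#' @return the statistic (percent).
#' @export
evaluation_parameter <- function(report, parameter = EVALUATION_PARAMETERS) {
  parameter <- match.arg(parameter)
  report[[parameter]]
}

#' @export
print.evaluation_report <- function(x, digits = 2, ...) {
  cat(sprintf("<evaluation_report> core %d of %d accessions, %d traits (alpha=%.2g)\n",
              x$n_core, x$n_initial, x$n_traits, x$alpha))
  vals <- unlist(x[EVALUATION_PARAMETERS])
  print(round(vals, digits))
  if (length(x$excluded)) {
    cat("excluded ratio terms:",
        paste(sprintf("%s(%d)", names(x$excluded),
                      vapply(x$excluded, nrow, 1L)), collapse = ", "), "\n")
  }
  invisible(x)
}
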