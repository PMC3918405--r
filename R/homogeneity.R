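# Validity assessment of evaluation statistics by homogeneous-population
# counting: one-way ANOVA of a statistic across sampling percentages,
# Tukey-Kramer pairwise comparisons, an insert-and-absorb compact letter
# display (CLD), and the homogeneous-population count = number of distinct
# letters used. More letters means the statistic distinguishes more
# sampling percentages, i.e. is a more valid yardstick.

#' Tukey multiple comparison with compact letter display
#'
#' One-way ANOVA followed by Tukey-Kramer pairwise tests (studentized
#' range distribution; reduces to Tukey HSD at equal group sizes) and the
#' insert-and-absorb letter algorithm. Groups sharing a letter are not
#' significantly different at `alpha`. Letters are assigned with groups
#' ordered by descending mean, so the "largest letter" indexes the number
#' of homogeneous populations.
#'
#' @param values numeric replicate values of one evaluation statistic.
#' @param groups group labels (e.g. sampling percentages), same length.
#' @param alpha significance level.
#' @return list of class `letter_display`: `letters` (named character,
#'   per group, mean-descending order), `means`, `n`,
#'   `homogeneous_populations` (number of distinct letters), `p_values`
#'   (pairwise matrix), `anova` (F statistic, df, p).
#' @export
tukey_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  values <- values[keep]; groups <- groups[keep]
  lev <- unique(groups)
  k <- length(lev)
  if (k < 2L) stop("need at least 2 groups")
  ni <- vapply(lev, function(g) sum(groups == g), 1L)
  if (any(ni < 2L)) {
    stop("groups with a single replicate: ",
         paste(lev[ni < 2L], collapse = ", "))
  }
  mi <- vapply(lev, function(g) mean(values[groups == g]), numeric(1))
  df_err <- length(values) - k
  sse <- sum((values - mi[match(groups, lev)])^2)
  mse <- sse / df_err
  grand <- mean(values)
  msb <- sum(ni * (mi - grand)^2) / (k - 1L)

  # pairwise Tukey-Kramer p-values; zero-MSE limit: unequal means separate
  p <- matrix(1, k, k, dimnames = list(lev, lev))
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      if (mse <= 0) {
        pv <- if (abs(mi[a] - mi[b]) < 1e-12) 1 else 0
      } else {
        q <- abs(mi[a] - mi[b]) / sqrt((mse / 2) * (1 / ni[a] + 1 / ni[b]))
        pv <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
      }
      p[a, b] <- p[b, a] <- pv
    }
  }

  ord <- order(mi, decreasing = TRUE)
  sig <- p[ord, ord, drop = FALSE] < alpha
  cld <- cld_insert_absorb(sig)
  f_stat <- if (mse > 0) msb / mse else Inf
  anova_p <- if (mse > 0) {
    stats::pf(f_stat, k - 1L, df_err, lower.tail = FALSE)
  } else if (any(sig)) 0 else 1
  structure(list(
    letters = stats::setNames(cld$letters, lev[ord]),
    means = mi[ord], n = ni[ord],
    homogeneous_populations = cld$n_letters,
    p_values = p,
    anova = c(F = f_stat, df1 = k - 1L, df2 = df_err, p = anova_p),
    alpha = alpha), class = "letter_display")
}

# Insert-and-absorb compact letter display on a significance matrix whose
# rows/cols are ordered (by descending mean). Returns one letter string
# per group. The surviving letter sets are exactly the maximal cliques of
# the non-significance graph.
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  sets <- list(seq_len(k))
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      if (!sig[a, b]) next
      for (s in seq_along(sets)) {
        if (a %in% sets[[s]] && b %in% sets[[s]]) {
          sets[[length(sets) + 1L]] <- setdiff(sets[[s]], a)
          sets[[s]] <- setdiff(sets[[s]], b)
        }
      }
      # absorb: drop sets contained in another; dedupe
      sets <- unique(lapply(sets, sort))
      keep <- vapply(seq_along(sets), function(i) {
        !any(vapply(seq_along(sets), function(j) {
          i != j && all(sets[[i]] %in% sets[[j]]) &&
            length(sets[[i]]) < length(sets[[j]])
        }, logical(1)))
      }, logical(1))
      sets <- sets[keep]
    }
  }
  sets <- sets[lengths(sets) > 0L]
  # order letters by the best-ranked member so letter 'a' sits on the
  # largest mean
  sets <- sets[order(vapply(sets, min, 1L), vapply(sets, max, 1L))]
  out <- character(k)
  for (s in seq_along(sets)) {
    lab <- make_letter(s)
    for (g in sets[[s]]) out[g] <- paste0(out[g], lab)
  }
  list(letters = out, n_letters = length(sets))
}

make_letter <- function(i) {
  # a..z, then aa, ab, ... for pathological cases
  if (i <= 26L) letters[i] else paste0(make_letter((i - 1L) %/% 26L),
                                       letters[((i - 1L) %% 26L) + 1L])
}

#' @export
print.letter_display <- function(x, ...) {
  cat(sprintf("<letter_display> %d homogeneous populations (alpha=%.2g)\n",
              x$homogeneous_populations, x$alpha))
  print(data.frame(group = names(x$letters), mean = round(x$means, 3),
                   n = x$n, letters = unname(x$letters)))
  invisible(x)
}

#' Enumerate the subcore-construction design
#'
#' The grid of (sampling percentage, replicate) combinations run for each
#' genetic distance when assessing statistic validity: by default 10-30%
#' in 1% steps with 4 replications, i.e. 84 subcore constructions.
#'
#' @param percentages sampling-percentage levels.
#' @param replications replicates per level.
#' @return data.frame with columns `percentage`, `replicate`.
#' @export
sampling_design <- function(percentages = seq(10, 30, by = 1),
                            replications = 4) {
  stopifnot(length(percentages) >= 1, replications >= 1)
  expand.grid(replicate = seq_len(replications), percentage = percentages,
              KEEP.OUT.ATTRS = FALSE)[, c("percentage", "replicate")]
}

#' Build the statistic table for a validity assessment
#'
#' Runs LDSS over the sampling design for each requested metric and
#' evaluates all seven statistics per subcore.
#'
#' @param matrix a [trait_matrix()].
#' @param metrics genetic distances to assess.
#' @param design a [sampling_design()] data.frame.
#' @param base_seed integer; the run for design row r under metric m uses
#'   seed `base_seed + 1000 * match(m) + r`.
#' @param alpha significance level passed to [evaluate_core()].
#' @return long data.frame: metric, percentage, replicate, parameter,
#'   value.
#' @export
evaluate_design <- function(matrix, metrics = "seuclid",
                            design = sampling_design(), base_seed = 1,
                            alpha = 0.05) {
  out <- vector("list", length(metrics) * nrow(design))
  idx <- 1L
  for (m in seq_along(metrics)) {
    for (r in seq_len(nrow(design))) {
      seed_r <- base_seed + 1000L * m + r
      sc <- ldss_sample(matrix, design$percentage[r], metric = metrics[m],
                        seed = seed_r)
      rep_ <- evaluate_core(matrix, sc$selected, alpha = alpha)
      out[[idx]] <- data.frame(
        metric = metrics[m], percentage = design$percentage[r],
        replicate = design$replicate[r],
        parameter = EVALUATION_PARAMETERS,
        value = unlist(rep_[EVALUATION_PARAMETERS], use.names = FALSE),
        stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  do.call(rbind, out)
}

#' Homogeneous-population counts per (metric, parameter)
#'
#' The validity table: for each metric and evaluation statistic, the
#' number of homogeneous populations from [tukey_groups()] across the
#' sampling percentages, plus a per-metric total. Larger counts mean the
#' statistic distinguishes more sampling percentages.
#'
#' @param param_table long data.frame as from [evaluate_design()]
#'   (columns metric, percentage, replicate, parameter, value).
#' @param alpha significance level.
#' @return data.frame of counts, rows = parameters (plus `Total`),
#'   columns = metrics.
#' @export
assess_validity <- function(param_table, alpha = 0.05) {
  needed <- c("metric", "percentage", "replicate", "parameter", "value")
  if (!all(needed %in% names(param_table))) {
    stop("param_table must have columns: ", paste(needed, collapse = ", "))
  }
  metrics <- unique(param_table$metric)
  params <- unique(param_table$parameter)
  pcts <- sort(unique(param_table$percentage))
  # completeness check over the (metric, parameter, percentage) grid
  have <- unique(param_table[, c("metric", "parameter", "percentage")])
  grid <- expand.grid(metric = metrics, parameter = params, percentage = pcts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$metric, d$parameter, d$percentage, sep = "|")
  missing <- setdiff(key(grid), key(have))
  if (length(missing)) {
    stop("missing design cells: ",
         paste(utils::head(missing, 10L), collapse = "; "))
  }
  counts <- matrix(NA_integer_, length(params), length(metrics),
                   dimnames = list(params, metrics))
  for (m in metrics) {
    for (p in params) {
      d <- param_table[param_table$metric == m & param_table$parameter == p, ]
      if (all(is.na(d$value))) { counts[p, m] <- NA_integer_; next }
      ld <- tukey_groups(d$value, d$percentage, alpha = alpha)
      counts[p, m] <- ld$homogeneous_populations
    }
  }
  out <- as.data.frame(counts)
  out <- rbind(out, Total = colSums(counts, na.rm = TRUE))
  out
}
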