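# Genotypic-value adjustment by fixed-effects least squares.
#
# Observed plot values are decomposed as
#   value ~ grand mean + environment + row(environment) + column(environment)
#           + genotype
# with sum-to-zero constraints on every factor (rows and columns sum to
# zero within their environment). The genotypic value of accession k is
# grand mean + genotype effect k, i.e. the accession's least-squares mean
# over a balanced field. GE effects are not modelled separately; they
# average out across environments into the genotype effect.
#
# This is a deliberate, documented stand-in for mixed-model prediction
# (MINQUE variance components + AUP genotype prediction): no shrinkage is
# applied, and a precomputed genotypic matrix from external mixed-model
# software can be supplied downstream instead.

#' Adjust observed multi-environment data to genotypic values
#'
#' Per trait, solves the additive fixed-effects model above by QR least
#' squares (one decomposition shared by all traits) and returns the
#' per-accession genotypic values plus the estimated effect tables.
#'
#' @param observed an `observed_dataset` (see [generate_germplasm()]) or a
#'   long data.frame with columns environment, replication, row, column,
#'   accession, trait, value.
#' @return list of class `adjustment_result`: `genotypic` (a
#'   [trait_matrix()]), `effects` (per-trait environment/row/column effect
#'   estimates), `method_label = "lsmeans-standin"`.
#' @export
adjust_genotypic <- function(observed) {
  rec <- if (inherits(observed, "observed_dataset")) observed$records
         else as.data.frame(observed)
  needed <- c("environment", "row", "column", "accession", "trait", "value")
  if (!all(needed %in% names(rec))) {
    stop("observed data must have columns: ", paste(needed, collapse = ", "))
  }
  envs <- sort(unique(rec$environment))
  accs <- unique(rec$accession)   # first-appearance order preserved
  traits <- unique(rec$trait)
  seen <- table(rec$accession[rec$trait == traits[1]], rec$environment[rec$trait == traits[1]])
  if (any(seen == 0)) {
    stop("every accession must be observed at least once per environment")
  }

  # records for one trait define the shared design
  base <- rec[rec$trait == traits[1], c("environment", "row", "column", "accession")]
  X <- adjustment_design(base, envs, accs)
  qrX <- qr(X$matrix)
  if (qrX$rank < ncol(X$matrix)) {
    bad <- colnames(X$matrix)[qrX$pivot[(qrX$rank + 1L):ncol(X$matrix)]]
    stop("design is rank deficient beyond the sum-to-zero constraints; ",
         "confounded columns: ", paste(utils::head(bad, 8L), collapse = ", "))
  }

  Y <- matrix(NA_real_, nrow(base), length(traits),
              dimnames = list(NULL, traits))
  key0 <- do.call(paste, c(base, sep = "\r"))
  for (t in traits) {
    rt <- rec[rec$trait == t, , drop = FALSE]
    key <- do.call(paste, c(rt[, c("environment", "row", "column", "accession")],
                            sep = "\r"))
    m <- match(key0, key)
    if (anyNA(m)) stop("trait ", t, " does not cover the same plots as ", traits[1])
    Y[, t] <- rt$value[m]
  }
  beta <- qr.coef(qrX, Y)

  g_cols <- X$geno_cols
  geno_eff <- beta[g_cols, , drop = FALSE]
  geno_full <- rbind(geno_eff, -colSums(geno_eff))  # last level = -sum
  genotypic <- sweep(geno_full, 2L, beta[1L, ], `+`) # grand mean + effect
  rownames(genotypic) <- accs

  effects <- list(
    environment = effect_table(beta, X$env_cols, envs),
    row = lapply(X$row_cols, function(ix) beta[ix, , drop = FALSE]),
    column = lapply(X$col_cols, function(ix) beta[ix, , drop = FALSE]))

  structure(list(genotypic = trait_matrix(genotypic),
                 effects = effects,
                 method_label = "lsmeans-standin"),
            class = "adjustment_result")
}

# Sum-to-zero design: intercept; environment (contr.sum); rows and columns
# coded within each environment (contr.sum over that environment's levels,
# zero elsewhere); genotype (contr.sum).
adjustment_design <- function(base, envs, accs) {
  n <- nrow(base)
  env_f <- match(base$environment, envs)
  blocks <- list(intercept = matrix(1, n, 1, dimnames = list(NULL, "(mean)")),
                 env = contr_sum_cols(env_f, length(envs), "env"))
  for (h in seq_along(envs)) {
    in_h <- env_f == h
    rlev <- sort(unique(base$row[in_h]))
    rmat <- matrix(0, n, max(length(rlev) - 1L, 0L),
                   dimnames = list(NULL, if (length(rlev) > 1L)
                     paste0("row.e", h, ".", rlev[-length(rlev)])))
    if (ncol(rmat)) {
      rmat[in_h, ] <- contr_sum_cols(match(base$row[in_h], rlev),
                                     length(rlev), "r")
    }
    blocks[[paste0("row.e", h)]] <- rmat
  }
  for (h in seq_along(envs)) {
    in_h <- env_f == h
    clev <- sort(unique(base$column[in_h]))
    cmat <- matrix(0, n, max(length(clev) - 1L, 0L),
                   dimnames = list(NULL, if (length(clev) > 1L)
                     paste0("col.e", h, ".", clev[-length(clev)])))
    if (ncol(cmat)) {
      cmat[in_h, ] <- contr_sum_cols(match(base$column[in_h], clev),
                                     length(clev), "c")
    }
    blocks[[paste0("col.e", h)]] <- cmat
  }
  blocks$geno <- contr_sum_cols(match(base$accession, accs),
                                length(accs), "geno")
  X <- do.call(cbind, blocks)
  ends <- cumsum(vapply(blocks, ncol, integer(1)))
  starts <- ends - vapply(blocks, ncol, integer(1)) + 1L
  ix <- function(name) {
    if (ends[name] < starts[name]) integer(0) else seq.int(starts[name], ends[name])
  }
  list(matrix = X,
       env_cols = ix("env"),
       row_cols = lapply(paste0("row.e", seq_along(envs)), ix),
       col_cols = lapply(paste0("col.e", seq_along(envs)), ix),
       geno_cols = ix("geno"))
}

# contr.sum dummy block for a factor given as integer codes 1..L
contr_sum_cols <- function(codes, L, prefix) {
  if (L <= 1L) return(matrix(0, length(codes), 0L))
  M <- matrix(0, length(codes), L - 1L,
              dimnames = list(NULL, paste0(prefix, seq_len(L - 1L))))
  for (k in seq_len(L - 1L)) M[codes == k, k] <- 1
  M[codes == L, ] <- -1
  M
}

effect_table <- function(beta, ix, levels) {
  if (!length(ix)) {
    return(matrix(0, 1, ncol(beta), dimnames = list(as.character(levels[1]),
                                                    colnames(beta))))
  }
  eff <- beta[ix, , drop = FALSE]
  out <- rbind(eff, -colSums(eff))
  rownames(out) <- as.character(levels)
  out
}

#' @export
print.adjustment_result <- function(x, ...) {
  cat(sprintf("<adjustment_result> method=%s, %d accessions x %d traits\n",
              x$method_label, nrow(x$genotypic), ncol(x$genotypic)))
  invisible(x)
}
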