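# Synthetic multi-environment germplasm trial generator.
#
# Observed values follow the additive genetic model
#   Y = mu + E_h + R_i(h) + C_j(h) + G_k + GE_hk + eps,
# with fixed environment/row/column effects, a random genotypic effect G
# drawn once per accession (multivariate normal across traits), a random
# genotype-by-environment effect GE per (accession, environment), and an
# i.i.d. residual per plot record. A controllable fraction of accessions
# are near-duplicates (a donor's genotype plus jitter), emulating the
# redundancy a core collection is meant to eliminate.

#' Configuration for the synthetic germplasm generator
#'
#' Defaults emulate a 168-accession cotton germplasm group scored for 20
#' quantitative traits in 2 environments (years) with 2 replications each,
#' on a 6-row x 80-column field per replication, with 30% redundant
#' accessions.
#'
#' @param n_accessions,n_traits collection dimensions.
#' @param n_environments number of environments (years).
#' @param n_replications replications per environment.
#' @param n_rows,n_columns field layout per replication.
#' @param mu per-trait population mean (recycled to `n_traits`).
#' @param var_G,var_GE,var_eps per-trait variance components, trait units
#'   squared (recycled).
#' @param env_effect_sd,row_effect_sd,col_effect_sd standard deviations of
#'   the fixed environment / row-within-environment / column-within-
#'   environment effects (drawn once, then treated as fixed).
#' @param trait_correlation accession-level trait correlation: either a
#'   single off-diagonal value (compound symmetry) or a full correlation
#'   matrix.
#' @param redundancy_fraction proportion of accessions that are
#'   near-duplicates of another accession, in `[0, 1)`.
#' @param redundancy_jitter sd (trait units) of the perturbation added to a
#'   duplicate's genotypic values; 0 gives exact copies.
#' @param independent_replication_layouts if `TRUE` (default) each
#'   replication within an environment is randomized separately; row and
#'   column effects are shared across replications within an environment
#'   either way.
#' @param seed RNG seed; the generator is bit-reproducible under a fixed
#'   seed.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_accessions = 168, n_traits = 20,
                             n_environments = 2, n_replications = 2,
                             n_rows = 6, n_columns = 80,
                             mu = 50, var_G = 100, var_GE = 10, var_eps = 20,
                             env_effect_sd = 5, row_effect_sd = 2,
                             col_effect_sd = 2, trait_correlation = 0.2,
                             redundancy_fraction = 0.3,
                             redundancy_jitter = 0.5,
                             independent_replication_layouts = TRUE,
                             seed = 1) {
  cfg <- list(
    n_accessions = as.integer(n_accessions), n_traits = as.integer(n_traits),
    n_environments = as.integer(n_environments),
    n_replications = as.integer(n_replications),
    n_rows = as.integer(n_rows), n_columns = as.integer(n_columns),
    mu = rep_len(mu, n_traits), var_G = rep_len(var_G, n_traits),
    var_GE = rep_len(var_GE, n_traits), var_eps = rep_len(var_eps, n_traits),
    env_effect_sd = env_effect_sd, row_effect_sd = row_effect_sd,
    col_effect_sd = col_effect_sd,
    trait_correlation = trait_correlation,
    redundancy_fraction = redundancy_fraction,
    redundancy_jitter = redundancy_jitter,
    independent_replication_layouts = isTRUE(independent_replication_layouts),
    seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_accessions >= 2, n_traits >= 1, n_environments >= 1,
              n_replications >= 1, n_rows >= 1, n_columns >= 1)
    if (any(var_G < 0) || any(var_GE < 0) || any(var_eps < 0)) {
      stop("variance components must be >= 0")
    }
    if (redundancy_fraction < 0 || redundancy_fraction >= 1) {
      stop("redundancy_fraction must be in [0, 1)")
    }
    if (n_accessions > n_rows * n_columns) {
      stop("field overflow: ", n_accessions, " accessions exceed ",
           n_rows * n_columns, " cells per replication")
    }
  })
  R <- correlation_matrix(cfg)
  if (!isSymmetric(R) || any(diag(R) != 1)) {
    stop("trait_correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("trait_correlation must be positive semidefinite")
  invisible(cfg)
}

correlation_matrix <- function(cfg) {
  R <- cfg$trait_correlation
  p <- cfg$n_traits
  if (is.matrix(R)) {
    if (!all(dim(R) == p)) stop("trait_correlation matrix must be ", p, "x", p)
    return(R)
  }
  out <- matrix(R, p, p)
  diag(out) <- 1
  out
}

#' Assign accessions to field cells
#'
#' One seeded random permutation per (environment, replication): each
#' accession occupies exactly one (row, column) cell per replication, and
#' surplus cells stay empty.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns environment, replication, row, column,
#'   accession.
#' @export
plant_layout <- function(config) {
  validate_synthetic_config(config)
  n_cells <- config$n_rows * config$n_columns
  ids <- sprintf("ACC%03d", seq_len(config$n_accessions))
  # layout stream derived from the config seed so generate_germplasm() and
  # a standalone plant_layout() call agree
  with_seed(config$seed + 101L, {
    out <- vector("list", config$n_environments * config$n_replications)
    idx <- 1L
    first_cells <- NULL
    for (h in seq_len(config$n_environments)) {
      for (r in seq_len(config$n_replications)) {
        if (r == 1L || config$independent_replication_layouts) {
          cells <- sample.int(n_cells, config$n_accessions)
        } else {
          cells <- first_cells
        }
        if (r == 1L) first_cells <- cells
        out[[idx]] <- data.frame(
          environment = h, replication = r,
          row = ((cells - 1L) %% config$n_rows) + 1L,
          column = ((cells - 1L) %/% config$n_rows) + 1L,
          accession = ids, stringsAsFactors = FALSE)
        idx <- idx + 1L
      }
    }
    do.call(rbind, out)
  })
}

#' Generate synthetic multi-environment trait data
#'
#' Draws fixed environment/row/column effects, per-accession genotypic
#' effects (multivariate normal across traits, with a redundant fraction
#' copied from donors plus jitter), per-(accession, environment) GE
#' effects, and per-record residuals, then assembles observed plot values
#' on the field layout.
#'
#' @param config a [synthetic_config()].
#' @return list with `observed` (class `observed_dataset`: long data.frame
#'   plus layout metadata) and `genotypic` (the true `trait_matrix`,
#'   `mu + G`, for oracle comparisons).
#' @export
generate_germplasm <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_accessions; p <- config$n_traits
  ids <- sprintf("ACC%03d", seq_len(n))
  trait_names <- sprintf("trait%02d", seq_len(p))
  layout <- plant_layout(config)

  with_seed(config$seed, {
    # fixed effects are deviations from mu: centered so E sums to zero over
    # environments and rows/columns sum to zero within each environment
    env_eff <- stats::rnorm(config$n_environments, 0, config$env_effect_sd)
    env_eff <- env_eff - mean(env_eff)
    row_eff <- matrix(stats::rnorm(config$n_environments * config$n_rows,
                                   0, config$row_effect_sd),
                      config$n_environments, config$n_rows)
    row_eff <- row_eff - rowMeans(row_eff)
    col_eff <- matrix(stats::rnorm(config$n_environments * config$n_columns,
                                   0, config$col_effect_sd),
                      config$n_environments, config$n_columns)
    col_eff <- col_eff - rowMeans(col_eff)

    # genotypic effects: distinct accessions drawn jointly across traits,
    # redundant ones copied from donors
    n_red <- as.integer(round_half_up(config$redundancy_fraction * n))
    n_distinct <- n - n_red
    D <- diag(sqrt(config$var_G), p)
    Sigma <- D %*% correlation_matrix(config) %*% D
    G <- matrix(0, n, p)
    G[seq_len(n_distinct), ] <-
      MASS::mvrnorm(n_distinct, mu = rep(0, p), Sigma = Sigma)
    donors <- integer(0)
    if (n_red > 0L) {
      donors <- sample.int(n_distinct, n_red, replace = TRUE)
      jit <- matrix(stats::rnorm(n_red * p, 0, config$redundancy_jitter),
                    n_red, p)
      G[n_distinct + seq_len(n_red), ] <- G[donors, , drop = FALSE] + jit
    }

    GE <- array(stats::rnorm(n * config$n_environments * p, 0,
                             rep(sqrt(config$var_GE), each = n * config$n_environments)),
                dim = c(n, config$n_environments, p))

    genotypic <- sweep(G, 2L, config$mu, `+`)
    dimnames(genotypic) <- list(ids, trait_names)

    acc_idx <- match(layout$accession, ids)
    n_rec <- nrow(layout)
    records <- vector("list", p)
    for (t in seq_len(p)) {
      eps <- stats::rnorm(n_rec, 0, sqrt(config$var_eps[t]))
      value <- config$mu[t] +
        env_eff[layout$environment] +
        row_eff[cbind(layout$environment, layout$row)] +
        col_eff[cbind(layout$environment, layout$column)] +
        G[acc_idx, t] +
        GE[cbind(acc_idx, layout$environment, rep(t, n_rec))] +
        eps
      records[[t]] <- data.frame(layout, trait = trait_names[t],
                                 value = value, stringsAsFactors = FALSE)
    }
    observed <- structure(
      list(records = do.call(rbind, records),
           layout_dim = c(rows = config$n_rows, columns = config$n_columns),
           donors = if (n_red) data.frame(accession = ids[n_distinct + seq_len(n_red)],
                                          donor = ids[donors],
                                          stringsAsFactors = FALSE)
                    else NULL),
      class = "observed_dataset")
    list(observed = observed,
         genotypic = trait_matrix(genotypic))
  })
}

#' @export
print.observed_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf(paste0("<observed_dataset> %d records: %d accessions, ",
                     "%d traits, %d environments x %d replications\n"),
              nrow(r), length(unique(r$accession)), length(unique(r$trait)),
              length(unique(r$environment)), length(unique(r$replication))))
  invisible(x)
}
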