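# Monte Carlo simulation of an evaluation statistic over the
# (sampling percentage x number of traits) grid.
#
# Per replication one trait permutation is drawn; the trait subset of
# size k is the first k traits of that permutation (nested prefixes, so
# adjacent trait counts share traits and the surface is smooth in k).
# For each (k, percentage) an LDSS subcore is built and the chosen
# statistic evaluated on the unstandardized values of those k traits.
# Because the LDSS removal stream does not depend on the stopping size,
# one stepwise run per (replication, k) records the subset passed through
# at every percentage - identical to independent runs sharing the seed.

#' Configuration for the Monte Carlo surface
#'
#' Defaults follow the study design: percentages 10-30% in 1% steps,
#' trait counts 1-20, 20 replications, seuclid distance, CR statistic.
#'
#' @param percentages sampling-percentage grid (ascending).
#' @param trait_counts trait-count grid (ascending).
#' @param replications Monte Carlo replications.
#' @param metric genetic distance for LDSS.
#' @param parameter evaluation statistic to record (usually `"CR"`).
#' @param base_seed integer; replication r uses seed `base_seed + r`.
#' @return list of class `surface_config`.
#' @export
surface_config <- function(percentages = seq(10, 30, by = 1),
                           trait_counts = 1:20, replications = 20,
                           metric = "seuclid", parameter = "CR",
                           base_seed = 1) {
  stopifnot(length(percentages) >= 1, length(trait_counts) >= 1,
            replications >= 1)
  if (is.unsorted(percentages) || is.unsorted(trait_counts)) {
    stop("grids must be sorted ascending")
  }
  structure(list(percentages = percentages,
                 trait_counts = as.integer(trait_counts),
                 replications = as.integer(replications),
                 metric = metric,
                 parameter = match.arg(parameter, EVALUATION_PARAMETERS),
                 base_seed = as.integer(base_seed)),
            class = "surface_config")
}

#' Simulate the evaluation-statistic surface
#'
#' @param matrix a [trait_matrix()] of genotypic values.
#' @param config a [surface_config()].
#' @return list of class `cr_surface`: `mean` (trait counts x percentages
#'   matrix of replicate means), `replicates` (3-d array with replication
#'   as third dimension), and the `config`.
#' @export
simulate_surface <- function(matrix, config = surface_config()) {
  kmax <- max(config$trait_counts)
  if (kmax > ncol(matrix)) {
    stop("trait grid max (", kmax, ") exceeds available traits (",
         ncol(matrix), ")")
  }
  # fail fast on infeasible target sizes
  for (p in config$percentages) target_size(nrow(matrix), p)

  pc <- config$percentages
  tc <- config$trait_counts
  reps <- array(NA_real_,
                dim = c(length(tc), length(pc), config$replications),
                dimnames = list(tc, pc, seq_len(config$replications)))
  p_min <- pc[1L]
  p_rest <- if (length(pc) > 1L) pc[-1L] else NULL
  for (r in seq_len(config$replications)) {
    seed_r <- config$base_seed + r
    perm <- with_seed(seed_r * 2L + 1L, sample.int(ncol(matrix)))
    for (ki in seq_along(tc)) {
      k <- tc[ki]
      sub <- trait_matrix(unclass(matrix)[, perm[seq_len(k)], drop = FALSE])
      sc <- ldss_sample(sub, p_min, metric = config$metric, seed = seed_r,
                        snapshot_percentages = p_rest)
      subsets <- c(list(sc$selected), unname(sc$snapshots))
      for (pi in seq_along(pc)) {
        rep_ <- evaluate_core(sub, subsets[[pi]])
        reps[ki, pi, r] <- rep_[[config$parameter]]
      }
    }
  }
  structure(list(mean = apply(reps, c(1L, 2L), mean),
                 replicates = reps, config = config),
            class = "cr_surface")
}

#' @export
print.cr_surface <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cr_surface> %s over %d trait counts x %d percentages, %d reps (%s)\n",
              cfg$parameter, length(cfg$trait_counts), length(cfg$percentages),
              cfg$replications, cfg$metric))
  invisible(x)
}

#' Flatten a surface to fitting data
#'
#' @param surface a `cr_surface`.
#' @return data.frame with columns `x` (sampling percentage), `y` (trait
#'   count), `z` (mean statistic).
#' @export
surface_points <- function(surface) {
  m <- surface$mean
  data.frame(
    x = rep(surface$config$percentages, each = nrow(m)),
    y = rep(surface$config$trait_counts, times = ncol(m)),
    z = as.vector(m))
}
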