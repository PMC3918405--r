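# End-to-end strategy runner: (simulate or load) -> adjust -> surface ->
# fit -> select -> invert -> validate, with every artifact written under
# one output directory and a JSON manifest recording seeds, parameters,
# and a config hash.

#' Default run configuration
#'
#' @param out_dir output directory for artifacts.
#' @param trait_matrix_path optional path to a precomputed genotypic
#'   trait matrix (e.g. mixed-model output from external software); when
#'   set, the synthetic generator and the adjustment stage are skipped.
#' @param observed_path optional path to a long-format observed dataset
#'   to adjust; ignored when `trait_matrix_path` is set.
#' @param metric genetic distance for LDSS.
#' @param parameter evaluation statistic driving the surface.
#' @param alpha significance level.
#' @param percentages,trait_counts,replications Monte Carlo surface grid.
#' @param cr_threshold threshold at which the selected formula is
#'   inverted.
#' @param r2_floor,error_tolerance formula selection rule, see
#'   [select_formula()].
#' @param families candidate family numbers.
#' @param fixed_family,fixed_theta optionally skip fitting and invert
#'   this family with these constants.
#' @param validate_percentages percentages for the treat-vs-CK check.
#' @param validate_seeds number of seeds for the treat-vs-CK check.
#' @param seed master seed; all stage seeds derive from it.
#' @param synthetic a [synthetic_config()] used when no input paths are
#'   given.
#' @return named list of class `run_config`.
#' @export
run_config <- function(out_dir = "corescale_run",
                       trait_matrix_path = NULL, observed_path = NULL,
                       metric = "seuclid", parameter = "CR", alpha = 0.05,
                       percentages = seq(10, 30, by = 1),
                       trait_counts = 1:20, replications = 20,
                       cr_threshold = 80, r2_floor = 0.70,
                       error_tolerance = 0.20, families = 1:12,
                       fixed_family = NULL, fixed_theta = NULL,
                       validate_percentages = NULL, validate_seeds = 10,
                       seed = 1, synthetic = synthetic_config()) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full optimal-sampling-percentage strategy
#'
#' @param config a [run_config()].
#' @return list of class `strategy_result` with the genotypic matrix,
#'   surface, fits, selected fit, optimal curve, validation comparison,
#'   and the manifest. Artifacts are written under `config$out_dir`.
#' @export
run_strategy <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", config$out_dir, ")", call. = FALSE)
    })
  }
  manifest <- list(package = "corescale",
                   version = as.character(utils::packageVersion("corescale")),
                   seed = config$seed,
                   metric = config$metric, parameter = config$parameter,
                   cr_threshold = config$cr_threshold,
                   config_hash = config_hash(config),
                   stages = list())

  genotypic <- stage("input", {
    if (!is.null(config$trait_matrix_path)) {
      manifest$stages$input <- list(source = "trait_matrix",
                                     path = config$trait_matrix_path)
      read_trait_matrix(config$trait_matrix_path)
    } else if (!is.null(config$observed_path)) {
      manifest$stages$input <- list(source = "observed",
                                     path = config$observed_path)
      adjust_genotypic(read_observed(config$observed_path))$genotypic
    } else {
      syn <- config$synthetic
      syn$seed <- config$seed
      manifest$stages$input <- list(source = "synthetic", seed = syn$seed)
      gen <- generate_germplasm(syn)
      write_observed(gen$observed, file.path(config$out_dir, "observed.tsv"))
      adj <- adjust_genotypic(gen$observed)
      adj$genotypic
    }
  })
  write_trait_matrix(genotypic, file.path(config$out_dir, "genotypic.tsv"))

  surface <- stage("surface", {
    cfg <- surface_config(percentages = config$percentages,
                          trait_counts = config$trait_counts,
                          replications = config$replications,
                          metric = config$metric,
                          parameter = config$parameter,
                          base_seed = config$seed * 1000L)
    manifest$stages$surface <- list(base_seed = cfg$base_seed,
                                     cells = length(cfg$percentages) *
                                       length(cfg$trait_counts),
                                     replications = cfg$replications)
    simulate_surface(genotypic, cfg)
  })
  utils::write.table(surface$mean,
                     file.path(config$out_dir, "surface.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)

  if (is.null(config$fixed_family)) {
    fits <- stage("fit", fit_families(surface, families = config$families,
                                      seed = config$seed))
    sel <- stage("select", select_formula(fits, r2_floor = config$r2_floor,
                                          error_tolerance = config$error_tolerance))
  } else {
    fits <- formula_fit(config$fixed_family, config$fixed_theta)
    sel <- fits
  }
  fit_tab <- as.data.frame(fits)
  fit_tab$theta <- vapply(fit_tab$theta, function(t)
    paste(sprintf("%.6g", t), collapse = ","), character(1))
  utils::write.table(fit_tab, file.path(config$out_dir, "fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$fit <- list(selected_family = sel$fn[1L],
                              theta = as.numeric(sel$theta[[1L]]))

  curve <- stage("invert", invert_at_threshold(
    sel, cr_star = config$cr_threshold,
    trait_counts = config$trait_counts,
    fitted_range = range(config$percentages)))
  utils::write.table(as.data.frame(curve),
                     file.path(config$out_dir, "optimal_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  val_pcts <- config$validate_percentages
  if (is.null(val_pcts)) {
    last <- curve$x_star[curve$traits == max(curve$traits)]
    val_pcts <- unique(c(if (length(last) && !is.na(last)) round(last, 2),
                         10, 15))
    # drop percentages that are infeasible for this collection size
    val_pcts <- Filter(function(p) {
      !inherits(tryCatch(target_size(nrow(genotypic), p),
                         error = function(e) e), "error")
    }, val_pcts)
  }
  validation <- stage("validate", compare_treat_ck(
    genotypic, percentages = val_pcts,
    seeds = config$seed * 100L + seq_len(config$validate_seeds),
    metric = config$metric, alpha = config$alpha))
  utils::write.table(validation$summary,
                     file.path(config$out_dir, "validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pca <- stage("pca", {
    core <- ldss_sample(genotypic, val_pcts[1L], metric = config$metric,
                        seed = config$seed)
    project_pca(genotypic, core$selected)
  })
  utils::write.table(pca$scores, file.path(config$out_dir, "pca_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest$stages$validate <- list(percentages = val_pcts,
                                   seeds = config$validate_seeds)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(genotypic = genotypic, surface = surface, fits = fits,
                 selected = sel, optimal_curve = curve,
                 validation = validation, pca = pca, manifest = manifest),
            class = "strategy_result")
}

config_hash <- function(config) {
  flat <- utils::capture.output(utils::str(config[order(names(config))]))
  # small stable FNV-1a style hash; no external digest dependency
  h <- 5381
  for (ch in utf8ToInt(paste(flat, collapse = "\n"))) {
    h <- (h * 33 + ch) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' @export
print.strategy_result <- function(x, ...) {
  cat("<strategy_result>\n")
  cat("  selected family:", x$selected$fn[1L], "\n")
  ok <- x$optimal_curve$defined
  cat(sprintf("  optimal percentage: %.2f%% (y=%d) .. %.2f%% (y=%d)\n",
              x$optimal_curve$percentage[ok][1L],
              x$optimal_curve$traits[ok][1L],
              utils::tail(x$optimal_curve$percentage[ok], 1L),
              utils::tail(x$optimal_curve$traits[ok], 1L)))
  invisible(x)
}
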