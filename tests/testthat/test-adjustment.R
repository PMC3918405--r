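make_noise_free <- function(seed = 7) {
  cfg <- synthetic_config(n_accessions = 24, n_traits = 3, n_rows = 4,
                          n_columns = 6, var_GE = 0, var_eps = 0,
                          redundancy_fraction = 0, seed = seed)
  generate_germplasm(cfg)
}

test_that("noise-free data with positional effects is recovered exactly", {
  g <- make_noise_free()
  adj <- adjust_genotypic(g$observed)
  expect_equal(adj$method_label, "lsmeans-standin")
  got <- unclass(adj$genotypic)[rownames(g$genotypic), ]
  expect_equal(got, unclass(g$genotypic), tolerance = 1e-10)
})

test_that("single environment without positional effects collapses to accession means", {
  cfg <- synthetic_config(n_accessions = 10, n_traits = 2, n_environments = 1,
                          n_replications = 2, n_rows = 2, n_columns = 5,
                          env_effect_sd = 0, row_effect_sd = 0,
                          col_effect_sd = 0, var_GE = 0, var_eps = 0,
                          redundancy_fraction = 0, seed = 21)
  g <- generate_germplasm(cfg)
  adj <- adjust_genotypic(g$observed)
  rec <- g$observed$records
  means <- tapply(rec$value, list(rec$accession, rec$trait), mean)
  expect_equal(unclass(adj$genotypic)[rownames(means), colnames(means)],
               unclass(means), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a constant added to one environment shifts all genotypic values uniformly", {
  g <- make_noise_free(seed = 31)
  adj0 <- adjust_genotypic(g$observed)
  shifted <- g$observed
  in_env1 <- shifted$records$environment == 1
  shifted$records$value[in_env1] <- shifted$records$value[in_env1] + 7
  adj1 <- adjust_genotypic(shifted)
  delta <- unclass(adj1$genotypic) - unclass(adj0$genotypic)
  # uniform shift of c / n_environments; pairwise differences unchanged
  expect_equal(max(delta) - min(delta), 0, tolerance = 1e-9)
  expect_equal(mean(delta), 7 / 2, tolerance = 1e-9)
})

test_that("permuting record order permutes nothing in the genotypic values", {
  g <- make_noise_free(seed = 41)
  adj0 <- adjust_genotypic(g$observed)
  perm <- g$observed
  set.seed(1)
  perm$records <- perm$records[sample.int(nrow(perm$records)), ]
  adj1 <- adjust_genotypic(perm)
  ids <- rownames(adj0$genotypic)
  trs <- colnames(adj0$genotypic)
  expect_equal(unclass(adj1$genotypic)[ids, trs],
               unclass(adj0$genotypic)[ids, trs], tolerance = 1e-9)
})

test_that("adjustment beats raw accession means under residual noise", {
  wins <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(n_accessions = 48, n_traits = 2, n_rows = 6,
                            n_columns = 8, var_eps = 30, var_GE = 5,
                            env_effect_sd = 6, row_effect_sd = 4,
                            col_effect_sd = 4, redundancy_fraction = 0,
                            seed = 500 + s)
    g <- generate_germplasm(cfg)
    adj <- adjust_genotypic(g$observed)
    rec <- g$observed$records
    raw <- tapply(rec$value, list(rec$accession, rec$trait), mean)
    truth <- unclass(g$genotypic)
    ids <- rownames(truth)
    cor_adj <- cor(as.vector(unclass(adj$genotypic)[ids, colnames(truth)]),
                   as.vector(truth))
    cor_raw <- cor(as.vector(unclass(raw)[ids, colnames(truth)]),
                   as.vector(truth))
    if (cor_adj > cor_raw) wins <- wins + 1L
  }
  expect_gt(wins, n_seeds / 2)
})

test_that("confounded designs and incomplete coverage are rejected", {
  g <- make_noise_free()
  rec <- g$observed$records
  # drop one accession from environment 2 entirely
  drop <- rec$accession == "ACC001" & rec$environment == 2
  expect_error(adjust_genotypic(structure(list(records = rec[!drop, ]),
                                          class = "observed_dataset")),
               "once per environment")
})
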