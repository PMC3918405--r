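test_that("noise-free configuration reproduces genotypic values exactly", {
  cfg <- synthetic_config(n_accessions = 12, n_traits = 3, n_environments = 1,
                          n_replications = 1, n_rows = 3, n_columns = 4,
                          var_GE = 0, var_eps = 0, env_effect_sd = 0,
                          row_effect_sd = 0, col_effect_sd = 0,
                          redundancy_fraction = 0, seed = 11)
  g <- generate_germplasm(cfg)
  rec <- g$observed$records
  truth <- unclass(g$genotypic)
  expect_equal(rec$value,
               truth[cbind(rec$accession, rec$trait)],
               tolerance = 1e-12)
})

test_that("paper-scale configuration yields the full record count", {
  cfg <- synthetic_config(seed = 5) # 168 x 20, 2 env x 2 reps, 6 x 80
  g <- generate_germplasm(cfg)
  expect_equal(nrow(g$observed$records), 168 * 20 * 4)
  expect_equal(dim(g$genotypic), c(168L, 20L))
  expect_setequal(unique(g$observed$records$environment), 1:2)
})

test_that("redundancy fraction yields the expected number of duplicate rows", {
  cfg <- synthetic_config(n_accessions = 8, n_traits = 4, n_rows = 3,
                          n_columns = 3, redundancy_fraction = 0.25,
                          redundancy_jitter = 0, seed = 2)
  g <- generate_germplasm(cfg)
  vals <- unclass(g$genotypic)
  dup <- duplicated(vals) | duplicated(vals, fromLast = TRUE)
  # 2 duplicates, each matching its donor row
  expect_equal(sum(duplicated(vals)), 2L)
  expect_true(all(tapply(seq_len(8), apply(vals, 1, paste, collapse = ","),
                         length) <= 3))
})

test_that("generator is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_accessions = 20, n_traits = 4, n_rows = 4,
                          n_columns = 6, seed = 9)
  g1 <- generate_germplasm(cfg)
  g2 <- generate_germplasm(cfg)
  expect_identical(g1$observed$records, g2$observed$records)
  expect_identical(unclass(g1$genotypic), unclass(g2$genotypic))
})

test_that("empirical genotypic variance converges to var_G", {
  cfg <- synthetic_config(n_accessions = 5000, n_traits = 2,
                          n_environments = 1, n_replications = 1,
                          n_rows = 50, n_columns = 100, var_G = 100,
                          redundancy_fraction = 0, trait_correlation = 0,
                          seed = 13)
  g <- generate_germplasm(cfg)
  v <- apply(unclass(g$genotypic), 2, var)
  expect_true(all(abs(v - 100) / 100 < 0.10))
})

test_that("plant layout is a seeded bijection onto field cells", {
  cfg <- synthetic_config(n_accessions = 4, n_traits = 1, n_rows = 2,
                          n_columns = 2, redundancy_fraction = 0, seed = 3)
  lay <- plant_layout(cfg)
  one <- lay[lay$environment == 1 & lay$replication == 1, ]
  expect_setequal(paste(one$row, one$column), c("1 1", "1 2", "2 1", "2 2"))
  expect_identical(plant_layout(cfg), lay)

  big <- synthetic_config(seed = 4)
  blay <- plant_layout(big)
  one <- blay[blay$environment == 1 & blay$replication == 1, ]
  expect_equal(nrow(one), 168L)
  expect_equal(6 * 80 - nrow(unique(one[c("row", "column")])), 312L)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_accessions = 10, n_rows = 2, n_columns = 4),
               "field overflow")
  expect_error(synthetic_config(var_G = -1), "variance")
  expect_error(synthetic_config(redundancy_fraction = 1), "redundancy_fraction")
  bad_cor <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(synthetic_config(n_traits = 2, trait_correlation = bad_cor,
                                n_accessions = 10, n_rows = 4, n_columns = 4),
               "positive semidefinite")
})
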