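test_that("identically distributed groups share one letter", {
  set.seed(1)
  vals <- rnorm(20, 50, 1)
  groups <- rep(1:5, each = 4)
  ld <- tukey_groups(vals, groups)
  expect_equal(ld$homogeneous_populations, 1L)
  expect_true(all(ld$letters == "a"))
})

test_that("widely separated tight groups are fully distinguished", {
  set.seed(2)
  vals <- c(rnorm(4, 0, 0.01), rnorm(4, 100, 0.01), rnorm(4, 200, 0.01))
  groups <- rep(c("low", "mid", "high"), each = 4)
  ld <- tukey_groups(vals, groups)
  expect_equal(ld$homogeneous_populations, 3L)
  # letters in mean-descending order: a, b, c
  expect_equal(unname(ld$letters), c("a", "b", "c"))
  expect_equal(names(ld$letters), c("high", "mid", "low"))
})

test_that("the largest-letter rule counts homogeneous populations", {
  # construct a chain where group means step by just over the Tukey
  # threshold so letters a..c appear
  set.seed(3)
  vals <- c(rnorm(6, 0, 1), rnorm(6, 6, 1), rnorm(6, 12, 1))
  ld <- tukey_groups(vals, rep(1:3, each = 6))
  expect_equal(ld$homogeneous_populations,
               length(unique(unlist(strsplit(ld$letters, "")))))
  expect_equal(max(unlist(strsplit(ld$letters, ""))),
               letters[ld$homogeneous_populations])
})

test_that("letter counts equal the brute-force maximal-clique construction", {
  n_match <- 0L
  for (s in 1:60) {
    set.seed(4000 + s)
    k <- sample(3:6, 1)
    n_i <- sample(3:5, 1)
    means <- sort(runif(k, 0, sample(c(2, 6, 20), 1)))
    vals <- unlist(lapply(means, function(m) rnorm(n_i, m, 1)))
    groups <- rep(seq_len(k), each = n_i)
    ld <- tukey_groups(vals, groups)
    oracle <- tukey_sig_matrix(vals, groups)
    ord <- order(oracle$means, decreasing = TRUE)
    expected <- brute_force_cld_count(oracle$sig[ord, ord])
    expect_equal(ld$homogeneous_populations, expected,
                 label = paste("instance", s))
    n_match <- n_match + 1L
  }
  expect_equal(n_match, 60L)
})

test_that("letter sets form contiguous blocks over mean-sorted groups", {
  for (s in 1:20) {
    set.seed(7000 + s)
    k <- sample(3:6, 1)
    vals <- unlist(lapply(sort(runif(k, 0, 8)), function(m) rnorm(4, m, 1)))
    ld <- tukey_groups(vals, rep(seq_len(k), each = 4))
    for (ch in unique(unlist(strsplit(ld$letters, "")))) {
      pos <- unname(which(vapply(strsplit(ld$letters, ""),
                                 function(x) ch %in% x, logical(1))))
      expect_equal(pos, seq(min(pos), max(pos)), label = paste("seed", s))
    }
  }
})

test_that("degenerate groups are handled per contract", {
  # zero variance everywhere with equal means: one letter, no error
  ld <- tukey_groups(rep(5, 12), rep(1:3, each = 4))
  expect_equal(ld$homogeneous_populations, 1L)
  # zero variance with distinct means: fully separated
  ld2 <- tukey_groups(rep(c(1, 2, 3), each = 4), rep(1:3, each = 4))
  expect_equal(ld2$homogeneous_populations, 3L)
  expect_error(tukey_groups(c(1, 2, 3), c(1, 1, 2)), "single replicate")
  expect_error(tukey_groups(c(1, 2), c(1, 1)), "at least 2 groups")
})

test_that("the sampling design enumerates percentage x replicate", {
  d <- sampling_design()
  expect_equal(nrow(d), 84L)
  expect_equal(sort(unique(d$percentage)), 10:30)
  expect_equal(max(d$replicate), 4L)
  small <- sampling_design(c(10, 20), 3)
  expect_equal(nrow(small), 6L)
})

test_that("assess_validity counts per metric and parameter with totals", {
  set.seed(11)
  pcts <- c(10, 20, 30)
  tab <- expand.grid(metric = c("m1", "m2"), percentage = pcts,
                     replicate = 1:4, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    rows[[i]] <- data.frame(
      metric = tab$metric[i], percentage = tab$percentage[i],
      replicate = tab$replicate[i],
      parameter = c("sep", "const"),
      value = c(tab$percentage[i] * 10 + rnorm(1, 0, 0.01),  # separates fully
                5 + rnorm(1, 0, 0.01)))                      # constant
  }
  long <- do.call(rbind, rows)
  counts <- assess_validity(long)
  expect_equal(counts["sep", "m1"], 3)
  expect_equal(counts["const", "m1"], 1)
  expect_equal(counts["Total", "m2"],
               counts["sep", "m2"] + counts["const", "m2"])
  expect_error(assess_validity(long[long$percentage != 20 | long$metric != "m1", ]),
               "missing design cells")
})

test_that("CR distinguishes more percentages than MD on redundant data", {
  cfg <- synthetic_config(n_accessions = 80, n_traits = 8, n_rows = 8,
                          n_columns = 10, redundancy_fraction = 0.3,
                          seed = 29)
  g <- generate_germplasm(cfg)
  design <- sampling_design(percentages = c(10, 15, 20, 25, 30),
                            replications = 4)
  wins <- 0L
  n_runs <- 10L
  for (s in seq_len(n_runs)) {
    tab <- evaluate_design(g$genotypic, metrics = "seuclid", design = design,
                           base_seed = 3000 * s)
    counts <- assess_validity(tab)
    if (counts["CR", "seuclid"] >= counts["MD", "seuclid"]) wins <- wins + 1L
  }
  expect_gt(wins, n_runs / 2)
})
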