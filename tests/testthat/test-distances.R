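test_that("standardization matches hand arithmetic and is shift invariant", {
  m <- trait_matrix(matrix(c(0, 8, 4, 2, 6, 4), 3, 2))
  p <- standardization_params(m)
  z <- standardize(m, p)
  expect_equal(colMeans(z), c(trait01 = 0, trait02 = 0))
  expect_equal(apply(z, 2, sd), c(trait01 = 1, trait02 = 1))

  shifted <- trait_matrix(unclass(m) + 100)
  expect_equal(unclass(standardize(shifted)), unclass(z), ignore_attr = TRUE)

  # value 8 with reference mean 4 and sd 2 -> z = 2
  ref <- trait_matrix(matrix(c(4 - 2, 4 + 2, 4), 3, 1)) # mean 4, sd 2
  tgt <- trait_matrix(matrix(c(8, 4), 2, 1))
  z2 <- standardize(tgt, standardization_params(ref))
  expect_equal(unclass(z2)[1, 1], 2)

  const <- trait_matrix(cbind(a = c(1, 1, 1), b = c(1, 2, 3)))
  expect_error(standardization_params(const), "zero-variance trait.*a")
})

test_that("metric definitions match hand-computed values", {
  m <- trait_matrix(rbind(c(0, 0), c(3, 4)), c("p", "q"))
  expect_equal(as.numeric(trait_distance(m, "euclid")), 5)
  expect_equal(as.numeric(trait_distance(m, "cityblock")), 7)

  # identical rows are at distance 0 under every metric
  dup <- trait_matrix(rbind(c(1, 2, 3), c(1, 2, 3), c(4, 1, 0)))
  for (met in c("euclid", "seuclid", "mahal", "cityblock", "cosine",
                "correlation")) {
    expect_equal(as.matrix(trait_distance(dup, met))[1, 2], 0,
                 tolerance = 1e-12, label = met)
  }

  # mahalanobis with identity covariance reduces to euclidean
  set.seed(1)
  x <- trait_matrix(matrix(rnorm(40), 10, 4))
  big <- matrix(rnorm(4000), 1000, 4)
  big <- scale(big) %*% solve(chol(cov(scale(big)))) # exactly unit covariance
  ref <- trait_matrix(big)
  expect_equal(as.numeric(trait_distance(x, "mahal", reference = ref)),
               as.numeric(trait_distance(x, "euclid")), tolerance = 1e-8)
})

test_that("seuclid equals euclid on the standardized matrix", {
  m <- random_traits(15, 4, seed = 3)
  d1 <- trait_distance(m, "seuclid")
  d2 <- trait_distance(standardize(m), "euclid")
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-12)
})

test_that("deleting an accession leaves a submatrix of the distances", {
  m <- random_traits(10, 3, seed = 5)
  for (met in c("euclid", "seuclid", "cityblock")) {
    D <- as.matrix(trait_distance(m, met))
    keep <- accessions(m)[-4]
    Dsub <- as.matrix(trait_distance(m[keep, ], met, reference = m))
    expect_equal(Dsub, D[keep, keep], tolerance = 1e-12, label = met)
  }
})

test_that("degenerate inputs for cosine/correlation raise errors", {
  z <- trait_matrix(rbind(c(0, 0), c(1, 2), c(2, 1)))
  expect_error(trait_distance(z, "cosine"), "zero-norm")
  flat <- trait_matrix(rbind(c(2, 2), c(1, 3), c(0, 5)))
  expect_error(trait_distance(flat, "correlation"), "zero-variance")
  one <- trait_matrix(matrix(c(1, 2, 3), 3, 1))
  expect_error(trait_distance(one, "mahal"), "at least 2 traits")
  expect_error(trait_distance(one, "correlation"), "at least 2 traits")
})

test_that("upgma agglomerates by average linkage", {
  # 3 points at pairwise distances (1, 5, 5): first merge at 1, second at
  # the average height 5
  D <- matrix(c(0, 1, 5,
                1, 0, 5,
                5, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- upgma(as.dist(D))
  expect_equal(tr$merges[[1]]$members_a, "a")
  expect_equal(tr$merges[[1]]$members_b, "b")
  expect_equal(tr$merges[[1]]$height, 1)
  expect_equal(tr$merges[[2]]$height, 5)
  expect_setequal(c(tr$merges[[2]]$members_a, tr$merges[[2]]$members_b),
                  c("a", "b", "c"))

  # equidistant points merge at one height
  E <- matrix(1, 4, 4); diag(E) <- 0
  treq <- upgma(as.dist(E))
  expect_true(all(abs(treq$heights - 1) < 1e-12))
})

test_that("upgma first merge is the globally closest pair and heights rise", {
  for (s in 1:20) {
    n <- sample(4:12, 1)
    m <- random_traits(n, 3, seed = 900 + s)
    d <- trait_distance(m, "euclid")
    tr <- upgma(d)
    D <- as.matrix(d); diag(D) <- Inf
    ix <- which(D == min(D), arr.ind = TRUE)[1, ]
    expect_setequal(c(tr$merges[[1]]$members_a, tr$merges[[1]]$members_b),
                    rownames(D)[ix])
    expect_true(all(diff(tr$heights) > -1e-9))
  }
})
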