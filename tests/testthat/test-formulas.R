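ref_theta6 <- c(a = 65.90, b = 5.12, c = 5.07, d = 4.24)

grid_xy <- function() {
  data.frame(x = rep(10:30, each = 20), y = rep(1:20, 21))
}

test_that("noiseless data from a family is recovered exactly", {
  g <- grid_xy()
  g$z <- 84.24 + 0.03 * g$x * g$y
  fits <- fit_families(g, families = 1)
  expect_true(fits$converged)
  expect_equal(unname(fits$theta[[1]]), c(84.24, 0.03), tolerance = 1e-6)
  expect_equal(fits$r2, 1, tolerance = 1e-9)
  expect_equal(fits$error, 0, tolerance = 1e-6)
})

test_that("noisy data from the log family recovers its constants", {
  g <- grid_xy()
  clean <- corescale:::formula_value(6, ref_theta6, g$x, g$y)
  rel_err <- matrix(NA_real_, 20, 4)
  r2s <- numeric(20)
  for (r in 1:20) {
    set.seed(600 + r)
    g$z <- clean + rnorm(nrow(g), 0, 0.1)
    fit <- fit_families(g, families = 6)
    rel_err[r, ] <- abs(fit$theta[[1]] - ref_theta6) / abs(ref_theta6)
    r2s[r] <- fit$r2
  }
  expect_true(all(apply(rel_err, 2, median) < 0.05))
  expect_true(all(r2s >= 0.98))
})

test_that("a less expressive family fits log-family data worse", {
  g <- grid_xy()
  set.seed(5)
  g$z <- corescale:::formula_value(6, ref_theta6, g$x, g$y) +
    rnorm(nrow(g), 0, 0.1)
  fits <- fit_families(g, families = c(2, 6))
  r2 <- setNames(fits$r2, fits$fn)
  expect_lt(r2[["2"]], r2[["6"]])
})

test_that("selection by size/error/r2 picks the compact log family", {
  # the published (size, error, r2) triples of all 12 candidates
  published <- data.frame(
    fn = 1:12,
    size = c(7, 9, 11, 12, 13, 15, 18, 20, 24, 26, 28, 34),
    error = c(0.389, 0.180, 0.161, 0.120, 0.114, 0.090, 0.083, 0.078,
              0.076, 0.075, 0.075, 0.075),
    r2 = c(0.7222, 0.9571, 0.9619, 0.9746, 0.9757, 0.9896, 0.9917, 0.9926,
           0.9932, 0.9934, 0.9934, 0.9935))
  sel <- select_formula(published)
  expect_equal(sel$fn, 6)

  single <- published[4, ]
  expect_equal(select_formula(single)$fn, 4)

  ties <- data.frame(fn = c(2, 6), size = c(9, 15), error = c(0.1, 0.1),
                     r2 = c(0.95, 0.95))
  expect_equal(select_formula(ties)$fn, 2)

  weak <- data.frame(fn = 1, size = 7, error = 1, r2 = 0.5)
  expect_error(select_formula(weak), "r2 >= 0.7")
})

test_that("threshold inversion reproduces the reference endpoints", {
  fit <- formula_fit(6, ref_theta6)
  curve <- suppressWarnings(invert_at_threshold(fit, 80, 1:20))
  expect_equal(curve$percentage[curve$traits == 1], 25.01)
  expect_equal(curve$percentage[curve$traits == 20], 6.07)
  expect_true(all(curve$defined))
  # x*(y) strictly decreasing in y
  expect_true(all(diff(curve$x_star) < 0))
  # inversion correctness: f(x*, y) = threshold
  back <- corescale:::formula_value(6, ref_theta6, curve$x_star, curve$traits)
  expect_true(all(abs(back - 80) < 1e-9))
  # extrapolation outside the fitted percentage grid is flagged
  expect_true(any(curve$extrapolated))
  expect_warning(invert_at_threshold(fit, 80, 1:20), "extrapolates")
})

test_that("closed-form and bisection inversions agree", {
  fit <- formula_fit(6, ref_theta6)
  a <- suppressWarnings(invert_at_threshold(fit, 80, 1:20, method = "closed"))
  b <- suppressWarnings(invert_at_threshold(fit, 80, 1:20,
                                            method = "bisection"))
  expect_true(all(abs(a$x_star - b$x_star) < 1e-6))
})

test_that("unattainable thresholds are flagged undefined, not fabricated", {
  fit <- formula_fit(1, c(84.24, 0.03)) # max on grid ~ 102
  curve <- suppressWarnings(
    invert_at_threshold(fit, 50, 1:3, search = c(1, 30),
                        fitted_range = c(10, 30)))
  # f(1,y) >= 84.27 > 50 everywhere: no root below
  expect_true(all(!curve$defined))
  expect_error(invert_at_threshold(formula_fit(2, c(59, 6)), 80,
                                   method = "closed"),
               "no closed-form")
})

test_that("family registry exposes twelve families with reference starts", {
  fams <- formula_families()
  expect_length(fams, 12L)
  expect_equal(vapply(fams, `[[`, 1L, "fn"), setNames(1:12, names(fams)))
  sizes <- vapply(fams, `[[`, 1L, "size")
  expect_true(all(diff(sizes) > 0))
  # every family evaluates finitely at its reference constants on the grid
  g <- grid_xy()
  for (f in fams) {
    z <- corescale:::formula_value(f$fn, f$start, g$x, g$y)
    expect_true(all(is.finite(z)), label = paste("family", f$fn))
    expect_true(all(z > 40 & z < 130), label = paste("family", f$fn))
  }
})
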