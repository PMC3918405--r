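# Candidate formula families for the CR surface, nonlinear fitting,
# model selection by size/error/R-squared, and inversion at a CR
# threshold to the optimal sampling percentage per trait count.
#
# x = sampling percentage (percent, 10-30 on the default grid),
# y = number of traits, f(x, y) = CR (percent). "log" is the natural
# logarithm throughout. Each family carries its published reference
# constants (used as fit starting values) and a fixed expression-tree
# size used by the selection rule; free parameters are refit to the
# simulated surface.

#' The twelve candidate formula families
#'
#' @return data.frame-like list (class `formula_families`); one element
#'   per family with `fn` (family number), `size` (expression complexity),
#'   `npar`, `start` (reference constants), `fun(theta, x, y)`,
#'   `text` (display form), and for families with a log/denominator a
#'   `guard(theta, x, y)` returning the margin that must stay positive.
#' @export
formula_families <- function() {
  fam <- list(
    list(fn = 1L, size = 7L, start = c(a = 84.24, b = 0.03),
         text = "a + b*x*y",
         fun = function(th, x, y) th[1] + th[2] * x * y),
    list(fn = 2L, size = 9L, start = c(a = 59.55, b = 5.95),
         text = "a + b*log(x*y)",
         fun = function(th, x, y) th[1] + th[2] * log(x * y),
         guard = function(th, x, y) x * y),
    list(fn = 3L, size = 11L, start = c(a = 70.37, b = 0.40, c = 5.46),
         text = "a + b*x + c*log(x*y)",
         fun = function(th, x, y) th[1] + th[2] * x + th[3] * log(x * y),
         guard = function(th, x, y) x * y),
    list(fn = 4L, size = 12L, start = c(a = 85.72, b = 5.40, c = -133.68),
         text = "a + b*log(y) + c/x",
         fun = function(th, x, y) th[1] + th[2] * log(y) + th[3] / x,
         guard = function(th, x, y) y),
    list(fn = 5L, size = 13L, start = c(a = 64.26, b = 5.39, c = 5.02),
         text = "a + b*log(x*y - c*y)",
         fun = function(th, x, y) th[1] + th[2] * log(x * y - th[3] * y),
         guard = function(th, x, y) x * y - th[3] * y),
    list(fn = 6L, size = 15L,
         start = c(a = 65.90, b = 5.12, c = 5.07, d = 4.24),
         text = "a + b*log(x*y - c*y - d)",
         fun = function(th, x, y) th[1] + th[2] * log(x * y - th[3] * y - th[4]),
         guard = function(th, x, y) x * y - th[3] * y - th[4]),
    list(fn = 7L, size = 18L,
         start = c(a = 69.88, b = -61.33, c = 4.56, d = -8.75),
         text = "a + (y + b)/x + c*log(x*y + d)",
         fun = function(th, x, y) th[1] + (y + th[2]) / x + th[3] * log(x * y + th[4]),
         guard = function(th, x, y) x * y + th[4]),
    list(fn = 8L, size = 20L,
         start = c(a = 92.17, b = 4.16, c = -291.40, d = 1.34, e = 2.90),
         text = "a + b*log(y) + c/(d + x + e*log(y))",
         fun = function(th, x, y) th[1] + th[2] * log(y) +
           th[3] / (th[4] + x + th[5] * log(y)),
         guard = function(th, x, y) pmin(y, abs(th[4] + x + th[5] * log(y)))),
    list(fn = 9L, size = 24L,
         start = c(a = 70.56, b = 0.09, c = 4.38, d = -29.63, e = -310.22),
         text = "a + b*y + c*log(x + x*y) + (d*y + e)/(x + x*y)",
         fun = function(th, x, y) th[1] + th[2] * y + th[3] * log(x + x * y) +
           (th[4] * y + th[5]) / (x + x * y),
         guard = function(th, x, y) x + x * y),
    list(fn = 10L, size = 26L,
         start = c(a = 77.94, b = 0.09, c = 3.10, d = -53.22, e = -323.37),
         text = "a + b*y + c*log(x*y) + (d*y + e)/(x + y)",
         fun = function(th, x, y) th[1] + th[2] * y + th[3] * log(x * y) +
           (th[4] * y + th[5]) / (x + y),
         guard = function(th, x, y) pmin(x * y, x + y)),
    list(fn = 11L, size = 28L,
         start = c(a = 78.65, b = 0.09, c = 3.01, d = -60.77, e = -345.54),
         text = "a + b*y + c*log(x*y) + (d*y + e)/(x + y + x*y)",
         fun = function(th, x, y) th[1] + th[2] * y + th[3] * log(x * y) +
           (th[4] * y + th[5]) / (x + y + x * y),
         guard = function(th, x, y) pmin(x * y, x + y + x * y)),
    list(fn = 12L, size = 34L,
         start = c(a = 81.00, b = 0.11, c = 2.63, d = -62.06, e = -472.15),
         text = "a + b*y + c*log(x*y) + (d*y + e)/(x + x*y + c*log(x*y))",
         fun = function(th, x, y) {
           lg <- th[3] * log(x * y)
           th[1] + th[2] * y + lg + (th[4] * y + th[5]) / (x + x * y + lg)
         },
         guard = function(th, x, y) {
           pmin(x * y, abs(x + x * y + th[3] * log(x * y)))
         }))
  names(fam) <- paste0("FN", vapply(fam, `[[`, 1L, "fn"))
  structure(fam, class = "formula_families")
}

# Evaluate family fn at parameters theta; out-of-domain points give NA.
formula_value <- function(fn, theta, x, y) {
  fam <- formula_families()[[paste0("FN", fn)]]
  ok <- rep(TRUE, length(x))
  if (!is.null(fam$guard)) ok <- fam$guard(theta, x, y) > 0
  out <- rep(NA_real_, length(x))
  if (any(ok)) out[ok] <- fam$fun(theta, x[ok], y[ok])
  out
}

#' Fit candidate formula families to a surface
#'
#' Nonlinear least squares (Levenberg-Marquardt) per family, multi-start
#' from the reference constants plus seeded perturbations. Points where a
#' family's log argument or denominator is non-positive incur a large
#' penalty residual; a family whose best fit still violates its domain on
#' the data is reported as failed.
#'
#' @param surface a `cr_surface` from [simulate_surface()], or a
#'   data.frame with columns x, y, z (see [surface_points()]).
#' @param families integer vector of family numbers (subset of 1:12).
#' @param n_starts extra perturbed starts per family.
#' @param seed seed for start perturbations.
#' @return data.frame of class `formula_fits`, sorted by descending r2:
#'   columns fn, size, error (MAE), rmse, r2, converged, plus the fitted
#'   parameters in the list column `theta`.
#' @export
fit_families <- function(surface, families = 1:12, n_starts = 6, seed = 1) {
  pts <- if (inherits(surface, "cr_surface")) surface_points(surface)
         else as.data.frame(surface)
  stopifnot(all(c("x", "y", "z") %in% names(pts)))
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  fams <- formula_families()[paste0("FN", families)]
  if (nrow(pts) < max(vapply(fams, function(f) length(f$start), 1L))) {
    stop("surface has fewer points than free parameters")
  }
  rows <- lapply(fams, function(fam) fit_one_family(fam, pts, n_starts, seed))
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(fn = r$fn, size = r$size, error = r$error, rmse = r$rmse,
               r2 = r$r2, converged = r$converged)
  }))
  out$theta <- lapply(rows, `[[`, "theta")
  out <- out[order(-out$r2), ]
  rownames(out) <- NULL
  class(out) <- c("formula_fits", "data.frame")
  out
}

fit_one_family <- function(fam, pts, n_starts, seed) {
  x <- pts$x; y <- pts$y; z <- pts$z
  penalty <- 1e3
  resid_fun <- function(th) {
    ok <- if (is.null(fam$guard)) rep(TRUE, length(x)) else fam$guard(th, x, y) > 1e-9
    r <- numeric(length(x))
    if (any(ok)) r[ok] <- z[ok] - fam$fun(th, x[ok], y[ok])
    if (any(!ok)) {
      viol <- if (is.null(fam$guard)) 0 else pmax(1e-9 - fam$guard(th, x, y)[!ok], 0)
      r[!ok] <- penalty * (1 + viol)
    }
    r[!is.finite(r)] <- penalty * 10
    r
  }
  starts <- list(fam$start)
  extra <- with_seed(seed + fam$fn, {
    lapply(seq_len(n_starts), function(i) {
      fam$start * (1 + stats::rnorm(length(fam$start), 0, 0.15)) +
        stats::rnorm(length(fam$start), 0, 0.05)
    })
  })
  starts <- c(starts, extra)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || sse < best$sse) best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best)) {
    return(list(fn = fam$fn, size = fam$size, error = NA_real_,
                rmse = NA_real_, r2 = NA_real_, converged = FALSE,
                theta = fam$start * NA))
  }
  th <- best$par
  fitted <- formula_value(fam$fn, th, x, y)
  ok <- !is.na(fitted)
  if (!all(ok)) {
    return(list(fn = fam$fn, size = fam$size, error = NA_real_,
                rmse = NA_real_, r2 = NA_real_, converged = FALSE,
                theta = th))
  }
  res <- z - fitted
  list(fn = fam$fn, size = fam$size,
       error = mean(abs(res)), rmse = sqrt(mean(res^2)),
       r2 = 1 - sum(res^2) / sum((z - mean(z))^2),
       converged = TRUE, theta = th)
}

#' Select a formula by size, error, and R-squared
#'
#' Fits with `r2` below the floor are dropped; among the survivors whose
#' error is within `error_tolerance` of the best error, the smallest
#' `size` wins (ties broken by higher r2). This encodes the working rule:
#' reject simple families with high error and low R-squared, reject
#' complex families whose extra accuracy is marginal.
#'
#' @param fits a `formula_fits` data.frame (or any data.frame with
#'   columns fn, size, error, r2).
#' @param r2_floor minimum r2.
#' @param error_tolerance relative slack on the best error (0.20 = within
#'   20%).
#' @return the selected row (one-row data.frame).
#' @export
select_formula <- function(fits, r2_floor = 0.70, error_tolerance = 0.20) {
  fits <- as.data.frame(fits)
  ok <- !is.na(fits$r2) & fits$r2 >= r2_floor & !is.na(fits$error)
  if (!any(ok)) {
    stop("no candidate formula reached r2 >= ", r2_floor,
         "; enlarge the simulation grid or replications")
  }
  cand <- fits[ok, , drop = FALSE]
  best_err <- min(cand$error)
  cand <- cand[cand$error <= best_err * (1 + error_tolerance), , drop = FALSE]
  cand <- cand[order(cand$size, -cand$r2), , drop = FALSE]
  cand[1L, , drop = FALSE]
}

#' Build a formula fit from fixed constants
#'
#' Wraps published or otherwise externally supplied constants as a fit
#' row, without refitting; useful for inverting a reference formula.
#'
#' @param fn family number (1-12).
#' @param theta parameter vector of the family's arity.
#' @return one-row `formula_fits` data.frame (error/r2 `NA`).
#' @export
formula_fit <- function(fn, theta) {
  fam <- formula_families()[[paste0("FN", fn)]]
  if (is.null(fam)) stop("unknown family: ", fn)
  if (length(theta) != length(fam$start)) {
    stop("family ", fn, " takes ", length(fam$start), " parameters")
  }
  out <- data.frame(fn = fam$fn, size = fam$size, error = NA_real_,
                    rmse = NA_real_, r2 = NA_real_, converged = NA)
  out$theta <- list(stats::setNames(as.numeric(theta), names(fam$start)))
  class(out) <- c("formula_fits", "data.frame")
  out
}

#' Invert a fitted formula at a CR threshold
#'
#' Solves `f(x, y) = cr_star` for the sampling percentage x at each trait
#' count y. Family 6 has the closed form
#' `x = (exp((cr* - a)/b) + c*y + d) / y`; other families (or
#' `method = "bisection"`) use monotone root bracketing with
#' [stats::uniroot()]. Cells with no root in the search domain are
#' flagged undefined; solutions outside `fitted_range` are flagged as
#' extrapolated.
#'
#' @param fit one-row `formula_fits` data.frame (from [fit_families()],
#'   [select_formula()] or [formula_fit()]).
#' @param cr_star threshold value of the statistic (percent).
#' @param trait_counts trait counts y at which to invert.
#' @param method `"auto"` (closed form when available), `"closed"`, or
#'   `"bisection"`.
#' @param fitted_range x-range of the data the formula was fitted on,
#'   used only for the extrapolation flag.
#' @param search x-interval for bisection.
#' @return data.frame of class `optimal_curve`: traits, x_star
#'   (unrounded), percentage (x_star rounded to 2 decimals), defined,
#'   extrapolated; attributes `cr_star`, `fn`, `theta`.
#' @export
invert_at_threshold <- function(fit, cr_star = 80, trait_counts = 1:20,
                                method = c("auto", "closed", "bisection"),
                                fitted_range = c(10, 30),
                                search = c(1e-6, 1e4)) {
  method <- match.arg(method)
  fit <- as.data.frame(fit)[1L, ]
  fn <- fit$fn
  th <- fit$theta[[1L]]
  closed_available <- fn == 6L
  if (method == "closed" && !closed_available) {
    stop("no closed-form inversion for family ", fn)
  }
  use_closed <- closed_available && method != "bisection"

  x_star <- rep(NA_real_, length(trait_counts))
  for (i in seq_along(trait_counts)) {
    y <- trait_counts[i]
    if (use_closed) {
      xs <- (exp((cr_star - th[1]) / th[2]) + th[3] * y + th[4]) / y
      # a sampling percentage must be positive and inside the log's domain
      if (is.finite(xs) && xs > 0 && xs * y - th[3] * y - th[4] > 0) {
        x_star[i] <- xs
      }
    } else {
      g <- function(x) formula_value(fn, th, x, y) - cr_star
      lo <- search[1]; hi <- search[2]
      # shrink the bracket to the formula's domain at this y
      grid <- exp(seq(log(lo), log(hi), length.out = 200L))
      vals <- vapply(grid, g, numeric(1))
      okv <- which(!is.na(vals))
      if (length(okv) < 2L) next
      below <- okv[vals[okv] < 0]
      above <- okv[vals[okv] > 0]
      exact <- okv[vals[okv] == 0]
      if (length(exact)) { x_star[i] <- grid[exact[1L]]; next }
      if (!length(below) || !length(above)) next
      lo_i <- max(below[below < min(above)], -Inf)
      if (!is.finite(lo_i)) next
      hi_i <- min(above[above > lo_i])
      root <- tryCatch(
        stats::uniroot(g, lower = grid[lo_i], upper = grid[hi_i],
                       tol = 1e-12)$root,
        error = function(e) NA_real_)
      x_star[i] <- root
    }
  }
  out <- data.frame(traits = trait_counts,
                    x_star = x_star,
                    percentage = round(x_star, 2L),
                    defined = !is.na(x_star),
                    extrapolated = !is.na(x_star) &
                      (x_star < fitted_range[1] | x_star > fitted_range[2]))
  if (any(out$extrapolated)) {
    warning("optimal percentage extrapolates outside the fitted range [",
            fitted_range[1], ", ", fitted_range[2], "] for trait counts: ",
            paste(out$traits[out$extrapolated], collapse = ", "))
  }
  attr(out, "cr_star") <- cr_star
  attr(out, "fn") <- fn
  attr(out, "theta") <- th
  class(out) <- c("optimal_curve", "data.frame")
  out
}

#' @export
print.formula_fits <- function(x, ...) {
  df <- x
  class(df) <- "data.frame"
  df$theta <- vapply(df$theta, function(t)
    paste(sprintf("%.4g", t), collapse = ", "), character(1))
  print(df)
  invisible(x)
}
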