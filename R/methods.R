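#' Predict from a TPST fit
#'
#' Evaluates the fitted spline at new locations.  Points outside the mesh
#' yield `NA`.  Points on shared faces are evaluated in the lowest-index
#' containing tetrahedron (the value is identical from either side for a
#' `C^0`-or-smoother fit, up to round-off).
#'
#' @param object a [tpst()] fit.
#' @param newdata n x 3 matrix or data frame of locations (columns x, y, z);
#'   default: the training locations.
#' @param ... unused.
#' @return numeric vector of predictions (`NA` = outside the domain).
#' @export
predict.tpst <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 3L)
  p <- as_xyz_matrix(newdata)
  des <- design_matrix(object$space, p)
  out <- as.numeric(des$B %*% object$gamma)
  out[des$outside] <- NA_real_
  out
}

#' @export
fitted.tpst <- function(object, ...) object$fitted

#' @export
residuals.tpst <- function(object, ...) object$residuals

#' Spline coefficients of a TPST fit
#'
#' Returns the full per-tetrahedron Bernstein coefficient vector
#' `gamma = Q2 theta` (length `N * C(d+3, 3)`, blocks in
#' [multiindex_table()] order); the reduced coefficients `theta` are attached
#' as attribute `"theta"`.
#'
#' @param object a [tpst()] fit.
#' @param ... unused.
#' @export
coef.tpst <- function(object, ...) {
  structure(object$gamma, theta = object$theta)
}

#' @export
print.tpst <- function(x, ...) {
  cat(sprintf("TPST fit: S_%d^%d on %d tets, n = %d in-domain points\n",
              x$space$d, x$space$r, x$space$N, x$n_used))
  cat(sprintf("  rho = %.4g%s, edf = %.2f, RSS = %.4g, energy = %.4g\n",
              x$rho,
              if (!is.null(x$selection))
                paste0(" (", x$selection$method, "-selected)") else "",
              x$edf, x$rss, x$energy))
  cat(sprintf("  reduced dimension q = %d (of %d raw coefficients)\n",
              x$q, x$raw_dim))
  if (x$ridge_used > 0)
    cat(sprintf("  note: ridge %.3g applied (singular reduced system)\n",
                x$ridge_used))
  invisible(x)
}

#' @export
summary.tpst <- function(object, ...) {
  s <- list(
    d = object$space$d, r = object$space$r, N = object$space$N,
    n_used = object$n_used, q = object$q, raw_dim = object$raw_dim,
    rho = object$rho, edf = object$edf, rss = object$rss,
    sigma = sqrt(object$rss / max(1, object$n_used - object$edf)),
    energy = object$energy, gcv = object$gcv,
    compression = object$n_used / object$q,
    selection = object$selection, ridge_used = object$ridge_used,
    resid_summary = summary(object$residuals)
  )
  class(s) <- "summary.tpst"
  s
}

#' @export
print.summary.tpst <- function(x, ...) {
  cat(sprintf("Trivariate penalized spline fit (d = %d, r = %d)\n", x$d, x$r))
  cat(sprintf("  mesh: %d tetrahedra; data: %d in-domain points\n",
              x$N, x$n_used))
  cat(sprintf("  coefficients: %d raw, %d free (compression n/q = %.1f)\n",
              x$raw_dim, x$q, x$compression))
  cat(sprintf("  rho = %.4g, edf = %.2f, GCV = %.4g\n", x$rho, x$edf, x$gcv))
  cat(sprintf("  RSS = %.4g, residual scale = %.4g, roughness energy = %.4g\n",
              x$rss, x$sigma, x$energy))
  if (!is.null(x$selection)) {
    cat(sprintf("  rho selected by %s over %d grid points\n",
                x$selection$method, nrow(x$selection$table)))
  }
  cat("  residuals:\n")
  print(x$resid_summary)
  invisible(x)
}

#' Slice plot of a TPST fit
#'
#' Renders the fitted function on a regular grid over a constant-`z` slice of
#' the mesh bounding box (out-of-domain cells are blank).
#'
#' @param x a [tpst()] fit.
#' @param z slice height (default: mid-range of the mesh).
#' @param ngrid grid resolution per axis.
#' @param ... passed to [graphics::image()].
#' @export
plot.tpst <- function(x, z = NULL, ngrid = 80, ...) {
  v <- x$space$mesh$vertices
  if (is.null(z)) z <- mean(range(v[, 3]))
  xs <- seq(min(v[, 1]), max(v[, 1]), length.out = ngrid)
  ys <- seq(min(v[, 2]), max(v[, 2]), length.out = ngrid)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  vals <- predict(x, cbind(g, z))
  graphics::image(xs, ys, matrix(vals, ngrid, ngrid),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x", ylab = "y",
                  main = sprintf("TPST fit, z = %.3g", z), ...)
  invisible(x)
}

#' Simulate responses from a TPST fit (wild resampling)
#'
#' Draws new response vectors `W* = fitted + delta * residual` with
#' independent two-point golden-ratio wild weights `delta`, the same scheme
#' the wild bootstrap uses; valid under heteroscedastic noise.
#'
#' @param object a [tpst()] fit.
#' @param nsim number of response vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return n x nsim matrix of simulated responses.
#' @export
simulate.tpst <- function(object, nsim = 1, seed = 1, ...) {
  rs <- local_seed(seed)
  on.exit(restore_seed(rs))
  n <- object$n_used
  out <- matrix(0, n, nsim)
  for (b in seq_len(nsim))
    out[, b] <- object$fitted + wild_weights(n) * object$residuals
  out
}
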