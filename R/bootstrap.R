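#' Two-point wild-bootstrap weights
#'
#' Draws i.i.d. weights from the golden-ratio two-point law:
#' `delta = (1 + sqrt(5))/2` with probability `(5 - sqrt(5))/10` and
#' `delta = (1 - sqrt(5))/2` with probability `(5 + sqrt(5))/10`, which has
#' mean 0, variance 1, and third moment 1 — the classical wild-bootstrap
#' distribution for heteroscedastic regression.
#'
#' @param n number of draws.
#' @param seed optional integer seed (scoped: the caller's RNG stream is not
#'   disturbed); `NULL` uses the current stream.
#' @return numeric vector of length `n`.
#' @export
wild_weights <- function(n, seed = NULL) {
  if (n < 1) stop("'n' must be >= 1")
  if (!is.null(seed)) {
    rs <- local_seed(seed)
    on.exit(restore_seed(rs))
  }
  s5 <- sqrt(5)
  p_hi <- (5 - s5) / 10
  ifelse(stats::runif(n) < p_hi, (1 + s5) / 2, (1 - s5) / 2)
}

#' Wild-bootstrap standard errors for a TPST fit
#'
#' Estimates the pointwise standard error of the fitted function by the wild
#' bootstrap: (1) residuals `e_i = W_i - fitted_i` from the base fit;
#' (2) bootstrap responses `W*_i = fitted_i + delta_i e_i` with fresh
#' two-point weights per replicate; (3) refit with the identical mesh,
#' degree, smoothness, penalty parameter, and ridge (no re-selection of
#' `rho` inside the bootstrap); (4) `SE(p) = sqrt(mean_b (m*_b(p) -
#' mean_b m*_b(p))^2)` over the `B` replicates (divisor `B`).
#'
#' Because the design matrix and penalty are unchanged across replicates,
#' each refit reuses the stored Cholesky factor and costs one triangular
#' solve.
#'
#' @param fit a [tpst()] fit.
#' @param B number of bootstrap replicates (`>= 2`; default 100).
#' @param seed integer seed (results are deterministic given
#'   data/mesh/d/r/rho/B/seed).
#' @param query points at which to evaluate the SE: n x 3 matrix, or `NULL`
#'   for the fit's own data locations plus a seeded uniform in-domain grid of
#'   `n_grid` points.
#' @param n_grid size of the default added query grid.
#' @return object of class `tpst_se`: list with `query` (points), `se`,
#'   `B`, `seed`, `replicates_ok` (logical flags), and the per-query
#'   bootstrap mean `mean_boot`.
#' @export
tpst_se <- function(fit, B = 100, seed = 1, query = NULL, n_grid = 500) {
  if (B < 2) stop("'B' must be >= 2")
  sys <- fit$system
  if (is.null(sys)) stop("fit does not carry its system (internal) data")
  if (is.null(query)) {
    grid <- sample_domain_points(fit$space$mesh, n_grid, seed = seed + 1L)
    query <- rbind(fit$x, grid)
  }
  if (is.null(dim(query))) query <- matrix(query, ncol = 3L)
  query <- as_xyz_matrix(query)

  des <- design_matrix(fit$space, query)
  BqQ2 <- des$B %*% sys$Q2  # query-point evaluation in reduced coordinates

  rs <- local_seed(seed)
  on.exit(restore_seed(rs))
  nq <- nrow(query)
  acc <- numeric(nq); acc2 <- numeric(nq)
  ok <- logical(B)
  n <- fit$n_used
  for (b in seq_len(B)) {
    delta <- wild_weights(n)
    wstar <- fit$fitted + delta * fit$residuals
    btw <- as.numeric(Matrix::crossprod(sys$BQ2, wstar))
    theta_b <- backsolve(fit$chol, backsolve(fit$chol, btw, transpose = TRUE))
    ok[b] <- all(is.finite(theta_b))
    if (!ok[b]) next
    mb <- as.numeric(BqQ2 %*% theta_b)
    acc <- acc + mb; acc2 <- acc2 + mb^2
  }
  nb <- sum(ok)
  if (nb < 0.9 * B)
    stop("more than 10% of bootstrap replicate fits failed (", B - nb,
         " of ", B, ")")
  mean_b <- acc / nb
  se <- sqrt(pmax(0, acc2 / nb - mean_b^2))
  se[des$outside] <- NA_real_
  structure(list(query = query, se = se, mean_boot = mean_b, B = B,
                 seed = seed, replicates_ok = ok),
            class = "tpst_se")
}

#' @export
print.tpst_se <- function(x, ...) {
  cat(sprintf("Wild-bootstrap SE map: %d query points, B = %d replicates\n",
              nrow(x$query), x$B))
  print(summary(x$se))
  invisible(x)
}

# seeded rejection sampler of uniform in-mesh points (used for default
# bootstrap query grids)
sample_domain_points <- function(mesh, n, seed = 1) {
  rs <- local_seed(seed)
  on.exit(restore_seed(rs))
  v <- mesh$vertices
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  out <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(out) < n && tries < 1000L) {
    m <- max(2L * (n - nrow(out)), 100L)
    cand <- cbind(stats::runif(m, lo[1], hi[1]), stats::runif(m, lo[2], hi[2]),
                  stats::runif(m, lo[3], hi[3]))
    inside <- !is.na(locate_points(mesh, cand))
    out <- rbind(out, cand[inside, , drop = FALSE])
    tries <- tries + 1L
  }
  if (nrow(out) < n) stop("could not sample enough in-domain points")
  out[seq_len(n), , drop = FALSE]
}
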