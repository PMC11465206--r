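#' Fit a trivariate penalized spline over a triangulation
#'
#' Fits the TPST estimator to a scattered 3D point cloud: the minimizer over
#' the spline space `S_d^r` of `sum_i (W_i - s(p_i))^2 + rho * E(s)`, where
#' `E(s)` is the integrated weighted squared-second-derivative roughness
#' penalty.  The `C^r` constraints `H gamma = 0` are removed by a null-space
#' reduction `gamma = Q2 theta`, giving the closed-form solution
#' `theta = (Q2' B' B Q2 + rho Q2' P Q2)^{-1} Q2' B' W`.
#'
#' With `rho = NULL` the penalty parameter is selected on a log-spaced grid
#' by generalized cross-validation (`select = "gcv"`, criterion
#' `n RSS / (n - edf)^2`) or by tetrahedron-block cross-validation
#' (`select = "blockcv"`: whole tetrahedra are randomly assigned to folds so
#' that spatially dependent points are held out together).  Ties prefer the
#' smaller `rho`.
#'
#' Points falling outside the mesh are dropped with a warning.  If the
#' reduced normal-equations matrix is numerically singular (e.g. data-free
#' tetrahedra at `rho = 0`), a small ridge `eps * mean(diag(A))` is added and
#' the fit is flagged (`ridge_used`); set `ridge = 0` to error out instead.
#'
#' @param x point locations: an n x 3 matrix/data frame (columns x, y, z).
#'   For the formula method, a formula `w ~ x + y + z`.
#' @param w responses (length n).
#' @param mesh a [tet_mesh()], or a [tpst_setup()] precompute (in which case
#'   `d`, `r`, `rank_tol` and `null_method` are taken from it).
#' @param d spline degree (default 3).
#' @param r smoothness order (default 1), `0 <= r < d`.
#' @param rho penalty parameter `>= 0`, or `NULL` to select.
#' @param select selection method when `rho` is `NULL`.
#' @param rho_grid optional grid of candidate `rho` values; default 20
#'   log-spaced points on `[1e-6, 1e4] * s` with the scale
#'   `s = tr(Q2'B'BQ2) / tr(Q2'PQ2)`.
#' @param folds number of block-CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param ridge ridge added when the system is singular: `NULL` (automatic
#'   `1e-10` relative ridge), a positive relative value, or `0` (strict:
#'   error on singularity).
#' @param rank_tol relative singular-value tolerance for the constraint
#'   null space.
#' @param null_method passed to [null_space_basis()].
#' @param data data frame for the formula method.
#' @param ... passed between methods.
#' @return An object of class `tpst`: list with `space`, `theta`, `gamma`,
#'   `rho`, `fitted`, `residuals`, `rss`, `energy`, `edf`, `gcv`, `q`,
#'   `n_used`, `used` (indices of the supplied points that fell inside the
#'   mesh), `ridge_used`, `selection` (per-`rho` table when selection was
#'   performed, with the fold assignment for block CV), and reusable
#'   internals for [predict.tpst()] and [tpst_se()].
#' @examples
#' mesh <- structured_mesh(c(2, 2, 2), rbind(c(0, 0, 0), c(1, 1, 1)))
#' set.seed(1)
#' p <- matrix(runif(3000), ncol = 3)
#' w <- sin(pi * p[, 1]) + p[, 2]^2 + rnorm(1000, sd = 0.1)
#' fit <- tpst(p, w, mesh, d = 2, r = 0)
#' fit
#' @export
tpst <- function(x, ...) UseMethod("tpst")

#' @rdname tpst
#' @export
tpst.formula <- function(x, data, mesh, ...) {
  mf <- stats::model.frame(x, data)
  w <- stats::model.response(mf)
  pts <- as.matrix(mf[, -1, drop = FALSE])
  if (ncol(pts) != 3L) stop("formula must have exactly 3 coordinate terms")
  fit <- tpst.default(pts, w, mesh, ...)
  fit$call <- match.call()
  fit
}

#' @rdname tpst
#' @export
tpst.default <- function(x, w, mesh, d = 3, r = 1, rho = NULL,
                         select = c("gcv", "blockcv"), rho_grid = NULL,
                         folds = 5, seed = 1, ridge = NULL,
                         rank_tol = 1e-9, null_method = "auto", ...) {
  select <- match.arg(select)
  setup <- if (inherits(mesh, "tpst_setup")) mesh
           else tpst_setup(mesh, d, r, rank_tol = rank_tol,
                           null_method = null_method)
  d <- setup$space$d
  sys <- tpst_system(setup, x, w)
  selection <- NULL
  if (is.null(rho)) {
    if (d < 2) {
      rho <- 0
    } else {
      if (is.null(rho_grid)) rho_grid <- default_rho_grid(sys)
      selection <- if (select == "gcv") gcv_table(sys, rho_grid, ridge)
                   else blockcv_table(sys, rho_grid, folds, seed, ridge)
      rho <- selection$best_rho
    }
  }
  if (rho < 0) stop("'rho' must be non-negative")
  if (rho > 0 && d < 2)
    stop("the roughness penalty requires degree d >= 2; use rho = 0")
  if (rho == 0 && sys$n_used < sys$q)
    stop("under-determined: ", sys$n_used, " in-domain points for ", sys$q,
         " free coefficients at rho = 0; use rho > 0 or a coarser mesh")
  sol <- solve_system(sys, rho, ridge)
  fit <- build_fit(sys, sol, rho)
  fit$selection <- selection
  fit$call <- match.call()
  fit
}

# ---- internal machinery ----------------------------------------------------

#' Precompute the data-independent part of a TPST fit
#'
#' Assembles everything that depends only on (mesh, degree, smoothness):
#' the smoothness constraints, their null-space basis, and the reduced
#' penalty matrix.  Passing the result to [tpst()] in place of `mesh` lets
#' replication studies (many point clouds on one mesh) skip this work.
#'
#' @inheritParams tpst.default
#' @return object of class `tpst_setup`.
#' @export
tpst_setup <- function(mesh, d = 3, r = 1, rank_tol = 1e-9,
                       null_method = "auto") {
  space <- spline_space(mesh, d, r)
  cons <- smoothness_constraints(space)
  nb <- null_space_basis(space, cons, rank_tol = rank_tol,
                         method = null_method)
  Pr <- NULL
  if (space$d >= 2) {
    P <- assemble_penalty(space)
    Pr <- as.matrix(Matrix::crossprod(nb$Q2, P %*% nb$Q2))
    Pr <- (Pr + t(Pr)) / 2
  }
  structure(list(space = space, cons = cons, nb = nb, Pr = Pr),
            class = "tpst_setup")
}

# Precompute everything that depends on (mesh, d, r, data) but not on rho.
tpst_system <- function(setup, x, w) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  x <- as_xyz_matrix(x)
  w <- as.numeric(w)
  if (nrow(x) != length(w)) stop("lengths of 'x' and 'w' differ")
  if (!all(is.finite(w)) || !all(is.finite(x))) stop("non-finite data")

  space <- setup$space
  des <- design_matrix(space, x)
  if (any(des$outside)) {
    warning(sum(des$outside), " point(s) outside the mesh dropped")
  }
  keep <- !des$outside
  Q2 <- setup$nb$Q2
  BQ2 <- des$B[keep, , drop = FALSE] %*% Q2
  Gr <- as.matrix(Matrix::crossprod(BQ2))
  list(space = space, x = x[keep, , drop = FALSE], w = w[keep],
       used = which(keep),
       tet = des$tet[keep], n_used = sum(keep), q = setup$nb$q,
       nb = setup$nb, H = setup$cons$H, Q2 = Q2, BQ2 = BQ2, Gr = Gr,
       Pr = setup$Pr,
       BtW = as.numeric(Matrix::crossprod(BQ2, w[keep])))
}

default_rho_grid <- function(sys, n_rho = 20) {
  s <- sum(diag(sys$Gr)) / max(sum(diag(sys$Pr)), .Machine$double.eps)
  exp(seq(log(1e-6 * s), log(1e4 * s), length.out = n_rho))
}

# Cholesky solve of (Gr + rho Pr [+ eps I]); adds a relative ridge on
# numerical singularity unless ridge == 0.
solve_system <- function(sys, rho, ridge = NULL, Gr = NULL, BtW = NULL) {
  if (is.null(Gr)) Gr <- sys$Gr
  if (is.null(BtW)) BtW <- sys$BtW
  A <- Gr
  if (rho > 0) A <- A + rho * sys$Pr
  ch <- tryCatch(chol(A), error = function(e) NULL)
  eps_used <- 0
  if (is.null(ch)) {
    if (!is.null(ridge) && ridge == 0) {
      empty <- setdiff(seq_len(sys$space$N), unique(sys$tet))
      stop("singular reduced system (strict mode); data-free tetrahedra: ",
           if (length(empty)) paste(utils::head(empty, 10), collapse = ", ")
           else "none")
    }
    rel <- if (is.null(ridge)) 1e-10 else ridge
    eps_used <- rel * mean(diag(A))
    ch <- chol(A + diag(eps_used, nrow(A)))
  }
  theta <- backsolve(ch, backsolve(ch, BtW, transpose = TRUE))
  list(theta = theta, chol = ch, ridge_used = eps_used, A = A)
}

exact_edf <- function(sol, Gr) {
  Ai <- chol2inv(sol$chol)
  sum(Ai * Gr)  # tr(A^{-1} Gr), both symmetric
}

hutchinson_edf <- function(sol, Gr, probes = 50, seed = 1) {
  q <- nrow(Gr)
  rs <- local_seed(seed)
  on.exit(restore_seed(rs))
  acc <- 0
  for (b in seq_len(probes)) {
    z <- sample(c(-1, 1), q, replace = TRUE)
    acc <- acc + sum(z * backsolve(sol$chol,
                      backsolve(sol$chol, Gr %*% z, transpose = TRUE)))
  }
  acc / probes
}

fit_stats <- function(sys, sol) {
  fitted <- as.numeric(sys$BQ2 %*% sol$theta)
  rss <- sum((sys$w - fitted)^2)
  en <- if (is.null(sys$Pr)) 0 else
    max(0, as.numeric(crossprod(sol$theta, sys$Pr %*% sol$theta)))
  edf <- if (sys$q <= 5000) exact_edf(sol, sys$Gr)
         else hutchinson_edf(sol, sys$Gr)
  list(fitted = fitted, rss = rss, energy = en, edf = edf)
}

build_fit <- function(sys, sol, rho) {
  st <- fit_stats(sys, sol)
  n <- sys$n_used
  gcv <- if (n > st$edf) n * st$rss / (n - st$edf)^2 else NA_real_
  structure(list(
    space = sys$space, rho = rho, theta = sol$theta,
    gamma = as.numeric(sys$Q2 %*% sol$theta),
    x = sys$x, w = sys$w, tet = sys$tet, used = sys$used,
    fitted = st$fitted, residuals = sys$w - st$fitted,
    rss = st$rss, energy = st$energy, edf = st$edf, gcv = gcv,
    q = sys$q, n_used = n, raw_dim = sys$space$raw_dim,
    rank_tol = sys$nb$rank_tol, null_method = sys$nb$method,
    ridge_used = sol$ridge_used,
    system = sys, chol = sol$chol
  ), class = "tpst")
}

gcv_table <- function(sys, rho_grid, ridge = NULL) {
  rho_grid <- sort(rho_grid)
  tab <- data.frame(rho = rho_grid, rss = NA_real_, edf = NA_real_,
                    gcv = NA_real_, valid = TRUE)
  for (s in seq_along(rho_grid)) {
    sol <- solve_system(sys, rho_grid[s], ridge)
    st <- fit_stats(sys, sol)
    tab$rss[s] <- st$rss; tab$edf[s] <- st$edf
    if (sys$n_used > st$edf) {
      tab$gcv[s] <- sys$n_used * st$rss / (sys$n_used - st$edf)^2
    } else tab$valid[s] <- FALSE
  }
  ok <- which(tab$valid)
  if (!length(ok)) stop("no valid rho in the grid (edf >= n everywhere)")
  best <- ok[which.min(tab$gcv[ok])]  # which.min takes the first = smallest rho
  list(method = "gcv", table = tab, best_rho = tab$rho[best])
}

#' Tetrahedron-block cross-validation fold assignment
#'
#' Randomly assigns the `N` tetrahedra of a mesh to `k` folds (every
#' tetrahedron in exactly one fold); each tetrahedron acts as one spatial 3D
#' block, so all points inside it are held out together.
#'
#' @param N number of tetrahedra.
#' @param k number of folds (`>= 2`).
#' @param seed integer seed.
#' @return integer vector of fold ids (length `N`).
#' @export
blockcv_folds <- function(N, k, seed = 1) {
  if (k < 2) stop("'k' must be >= 2")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs))
  sample(rep_len(seq_len(k), N))
}

blockcv_table <- function(sys, rho_grid, folds, seed, ridge = NULL) {
  rho_grid <- sort(rho_grid)
  fold_id <- blockcv_folds(sys$space$N, folds, seed)
  pt_fold <- fold_id[sys$tet]
  sse <- numeric(length(rho_grid)); held <- 0L
  ridged <- FALSE
  for (f in seq_len(folds)) {
    test <- which(pt_fold == f)
    if (!length(test)) next
    Bt <- sys$BQ2[test, , drop = FALSE]
    Gr_f <- sys$Gr - as.matrix(Matrix::crossprod(Bt))
    BtW_f <- sys$BtW - as.numeric(Matrix::crossprod(Bt, sys$w[test]))
    held <- held + length(test)
    for (s in seq_along(rho_grid)) {
      sol <- solve_system(sys, rho_grid[s], ridge, Gr = Gr_f, BtW = BtW_f)
      if (sol$ridge_used > 0) ridged <- TRUE
      pred <- as.numeric(Bt %*% sol$theta)
      sse[s] <- sse[s] + sum((sys$w[test] - pred)^2)
    }
  }
  tab <- data.frame(rho = rho_grid, cv = sse / held)
  best <- which.min(tab$cv)
  list(method = "blockcv", table = tab, best_rho = tab$rho[best],
       folds = fold_id, seed = seed, ridged = ridged)
}

#' Refit a TPST model with new responses on the identical design
#'
#' For fixed-design replication studies (Monte-Carlo noise replicates, or
#' repeated scans of the same voxel grid): the mesh, degree, smoothness,
#' penalty parameter, constraint reduction and Cholesky factor of the
#' original fit are reused, so a refit costs one triangular solve instead of
#' a full re-assembly.
#'
#' @param fit a [tpst()] fit.
#' @param w new response vector of length `fit$n_used`, observed at the
#'   fit's own (in-domain) locations.
#' @return a new `tpst` object at the same `rho`.
#' @export
tpst_refit <- function(fit, w) {
  sys <- fit$system
  if (is.null(sys)) stop("fit does not carry its system data")
  w <- as.numeric(w)
  if (length(w) != fit$n_used)
    stop("'w' must have length ", fit$n_used)
  sys$w <- w
  sys$BtW <- as.numeric(Matrix::crossprod(sys$BQ2, w))
  theta <- backsolve(fit$chol, backsolve(fit$chol, sys$BtW, transpose = TRUE))
  sol <- list(theta = theta, chol = fit$chol, ridge_used = fit$ridge_used)
  new_fit <- build_fit(sys, sol, fit$rho)
  new_fit$call <- match.call()
  new_fit
}

#' Effective degrees of freedom of a TPST fit
#'
#' The trace of the hat operator
#' `B Q2 (Q2'B'BQ2 + rho Q2'PQ2)^{-1} Q2'B'`, computed exactly through the
#' stored Cholesky factor when `q <= 5000`, otherwise by a seeded Hutchinson
#' trace estimator.
#'
#' @param fit a [tpst()] fit.
#' @param rho optional alternative penalty value (default: the fit's).
#' @return scalar effective degrees of freedom.
#' @export
effective_df <- function(fit, rho = NULL) {
  if (is.null(rho) || identical(rho, fit$rho)) return(fit$edf)
  sys <- fit$system
  sol <- solve_system(sys, rho)
  if (sys$q <= 5000) exact_edf(sol, sys$Gr) else hutchinson_edf(sol, sys$Gr)
}

# RNG scope helpers: run seeded code without clobbering the caller's stream
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
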