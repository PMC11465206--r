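#' Multi-index table of the degree-d trivariate Bernstein basis
#'
#' All non-negative integer quadruples `(i, j, k, l)` with
#' `i + j + k + l = d`, in lexicographic order with `i` outermost descending
#' (then `j`, then `k` descending).  The row number of an index in this table
#' is the canonical rank used for every serialized coefficient vector in the
#' package; `C(d+3, 3)` rows in total.
#'
#' @param d polynomial degree (`>= 0`).
#' @return integer matrix with columns `i`, `j`, `k`, `l`.
#' @examples
#' nrow(multiindex_table(2))  # choose(5, 3) = 10
#' @export
multiindex_table <- function(d) {
  if (d < 0) stop("'d' must be non-negative")
  d <- as.integer(d)
  out <- matrix(0L, choose(d + 3L, 3L), 4L)
  r <- 1L
  for (i in d:0) for (j in (d - i):0) for (k in (d - i - j):0) {
    out[r, ] <- c(i, j, k, d - i - j - k)
    r <- r + 1L
  }
  colnames(out) <- c("i", "j", "k", "l")
  out
}

# closed-form 1-based rank of (i,j,k,l) in multiindex_table(d)
multiindex_rank <- function(idx, d) {
  i <- idx[, 1]; j <- idx[, 2]; k <- idx[, 3]
  choose(d - i + 2L, 3L) + choose(d - i - j + 1L, 2L) + (d - i - j - k) + 1L
}

#' Trivariate Bernstein basis polynomial value
#'
#' `B^d_{ijkl}(b) = d!/(i! j! k! l!) * b1^i b2^j b3^k b4^l` evaluated at
#' barycentric coordinates `b`, with the convention `0^0 = 1`.
#'
#' @param d degree.
#' @param idx length-4 multi-index summing to `d`.
#' @param b barycentric coordinates: length-4 vector or n x 4 matrix.
#' @return numeric vector of basis values.
#' @export
bernstein_eval <- function(d, idx, b) {
  idx <- as.integer(idx)
  if (length(idx) != 4L || any(idx < 0L) || sum(idx) != d)
    stop("'idx' must be 4 non-negative integers summing to d")
  if (is.null(dim(b))) b <- matrix(b, ncol = 4L)
  coef <- exp(lgamma(d + 1) - sum(lgamma(idx + 1)))
  pw <- function(x, e) if (e == 0L) rep(1, length(x)) else x^e
  coef * pw(b[, 1], idx[1]) * pw(b[, 2], idx[2]) *
    pw(b[, 3], idx[3]) * pw(b[, 4], idx[4])
}

# all M basis values at barycentric rows b (n x 4) -> n x M matrix
bernstein_all <- function(d, b) {
  tbl <- multiindex_table(d)
  M <- nrow(tbl)
  n <- nrow(b)
  # power tables b_m^e for e = 0..d
  pows <- lapply(1:4, function(m) outer(b[, m], 0:d, `^`))
  for (m in 1:4) pows[[m]][, 1] <- 1  # enforce 0^0 = 1
  lcoef <- lgamma(d + 1) - rowSums(lgamma(tbl + 1))
  out <- matrix(0, n, M)
  for (r in seq_len(M))
    out[, r] <- exp(lcoef[r]) * pows[[1]][, tbl[r, 1] + 1L] *
      pows[[2]][, tbl[r, 2] + 1L] * pows[[3]][, tbl[r, 3] + 1L] *
      pows[[4]][, tbl[r, 4] + 1L]
  out
}

#' Evaluate a B-form polynomial on a tetrahedron
#'
#' Evaluates `s(p) = sum_{|idx| = d} gamma_idx B^d_idx(p)` for the Bernstein
#' coefficient block `gamma` relative to the tetrahedron `v`.  Points need not
#' lie inside the tetrahedron (the polynomial extends globally).  Two
#' algorithms are provided: direct basis summation (default) and the
#' de Casteljau recurrence, which is used as a numerical cross-check.
#'
#' @param gamma coefficient vector of length `C(d+3, 3)` in
#'   [multiindex_table()] order.
#' @param v 4 x 3 tetrahedron vertex matrix.
#' @param p length-3 vector or n x 3 matrix of evaluation points.
#' @param d degree.
#' @param method `"direct"` or `"decasteljau"`.
#' @return numeric vector of values.
#' @export
bform_eval <- function(gamma, v, p, d, method = c("direct", "decasteljau")) {
  method <- match.arg(method)
  M <- choose(d + 3, 3)
  if (length(gamma) != M)
    stop("coefficient block has length ", length(gamma), ", expected ", M)
  b <- barycentric_coords(v, p)
  if (method == "direct") {
    drop(bernstein_all(d, b) %*% gamma)
  } else {
    apply(b, 1L, function(bb) de_casteljau(gamma, bb, d))
  }
}

# de Casteljau: repeated degree reduction c_eta <- sum_t b_t c_{eta + e_t}
de_casteljau <- function(gamma, b, d) {
  cur <- gamma
  for (dd in d:1) {
    tbl_lo <- multiindex_table(dd - 1L)
    nxt <- numeric(nrow(tbl_lo))
    for (t in 1:4) {
      up <- tbl_lo; up[, t] <- up[, t] + 1L
      nxt <- nxt + b[t] * cur[multiindex_rank(up, dd)]
    }
    cur <- nxt
  }
  cur
}

#' Barycentric representation of a direction vector
#'
#' The barycentric-coordinate increment `a = b(p + u) - b(p)` of a Cartesian
#' direction `u`, which is constant in `p` and sums to zero.  Used by the
#' Bernstein directional-derivative recurrence.
#'
#' @param v 4 x 3 tetrahedron vertex matrix.
#' @param u length-3 direction vector.
#' @return length-4 numeric vector summing to 0.
#' @export
direction_barycentric <- function(v, u) {
  v <- as_xyz_matrix(v)
  A <- rbind(1, t(v))
  if (abs(det(A)) < .Machine$double.eps * max(1, max(abs(v)))^3)
    stop("degenerate tetrahedron: coplanar vertices")
  drop(solve(A, c(0, u)))
}

#' Directional derivative of a B-form (coefficient recurrence)
#'
#' The directional derivative of a degree-`d` B-form along a direction with
#' barycentric representation `a` is the degree-`(d-1)` B-form with
#' coefficients `d * (a1 g_{eta+e1} + a2 g_{eta+e2} + a3 g_{eta+e3} +
#' a4 g_{eta+e4})`.
#'
#' @param gamma degree-`d` coefficient block.
#' @param a length-4 direction barycentrics from [direction_barycentric()].
#' @param d degree (`>= 1`).
#' @return degree-`(d-1)` coefficient block.
#' @export
directional_derivative_coeffs <- function(gamma, a, d) {
  if (d < 1) stop("derivative of a degree-0 B-form is undefined here: d >= 1")
  M <- choose(d + 3, 3)
  if (length(gamma) != M) stop("coefficient block length mismatch")
  tbl_lo <- multiindex_table(d - 1L)
  out <- numeric(nrow(tbl_lo))
  for (t in 1:4) {
    up <- tbl_lo; up[, t] <- up[, t] + 1L
    out <- out + a[t] * gamma[multiindex_rank(up, d)]
  }
  d * out
}

# sparse matrix form of the directional-derivative recurrence:
# (M_{d-1} x M_d), mapping degree-d blocks to degree-(d-1) blocks
directional_derivative_matrix <- function(a, d) {
  tbl_lo <- multiindex_table(d - 1L)
  mlo <- nrow(tbl_lo)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (t in 1:4) {
    up <- tbl_lo; up[, t] <- up[, t] + 1L
    ii <- c(ii, seq_len(mlo))
    jj <- c(jj, multiindex_rank(up, d))
    xx <- c(xx, rep(d * a[t], mlo))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(mlo, choose(d + 3, 3)))
}

#' Cartesian partial-derivative operator on B-form coefficients
#'
#' Linear map taking the degree-`d` Bernstein coefficient block of a
#' polynomial on tetrahedron `v` to the degree-`(d - |alpha|)` block of its
#' partial derivative `D^alpha = d^|alpha| / dx^a1 dy^a2 dz^a3`, composed
#' from directional derivatives along the coordinate axes (composition order
#' is immaterial).  Supports `|alpha| <= 2`.
#'
#' @param v 4 x 3 tetrahedron vertex matrix.
#' @param d degree (`>= |alpha|`).
#' @param alpha length-3 non-negative integer vector, `sum(alpha) <= 2`.
#' @return sparse matrix of dimension `C(d-|alpha|+3, 3) x C(d+3, 3)`.
#' @export
cartesian_derivative_operator <- function(v, d, alpha) {
  alpha <- as.integer(alpha)
  if (length(alpha) != 3L || any(alpha < 0L)) stop("'alpha' must be 3 non-negative integers")
  ord <- sum(alpha)
  if (ord > 2L) stop("only derivative orders |alpha| <= 2 are supported")
  if (d < ord) stop("need degree d >= |alpha|")
  axes <- rep(1:3, times = alpha)
  M <- choose(d + 3, 3)
  G <- Matrix::Diagonal(M)
  dd <- d
  for (ax in axes) {
    u <- c(0, 0, 0); u[ax] <- 1
    a <- direction_barycentric(v, u)
    G <- directional_derivative_matrix(a, dd) %*% G
    dd <- dd - 1L
  }
  G
}

# degree elevation: degree-d block -> equivalent degree-(d+1) block
degree_elevate <- function(gamma, d) {
  tbl_hi <- multiindex_table(d + 1L)
  out <- numeric(nrow(tbl_hi))
  for (t in 1:4) {
    dn <- tbl_hi; dn[, t] <- dn[, t] - 1L
    ok <- dn[, t] >= 0L
    out[ok] <- out[ok] + tbl_hi[ok, t] / (d + 1) *
      gamma[multiindex_rank(dn[ok, , drop = FALSE], d)]
  }
  out
}

#' Convert an analytic function to B-form on a tetrahedron
#'
#' Interpolates `f` at the degree-`d` domain-point lattice
#' `(i v1 + j v2 + k v3 + l v4) / d` and solves for the Bernstein
#' coefficients; exact for polynomials of total degree `<= d`.
#'
#' @param v 4 x 3 tetrahedron vertex matrix.
#' @param d degree.
#' @param f function taking an n x 3 matrix and returning n values.
#' @return coefficient block of length `C(d+3, 3)`.
#' @export
bform_from_function <- function(v, d, f) {
  v <- as_xyz_matrix(v)
  tbl <- multiindex_table(d)
  bary <- tbl / d
  pts <- bary %*% v
  Vmat <- bernstein_all(d, bary)
  vals <- f(pts)
  drop(solve(Vmat, vals))
}

#' Spline space of piecewise polynomials on a triangulation
#'
#' Describes the space `S_d^r` of piecewise degree-`d` polynomials on the
#' mesh with global `C^r` smoothness, `0 <= r < d`.  Coefficient vectors are
#' laid out as `N` consecutive per-tetrahedron blocks of length
#' `M = C(d+3, 3)` in [multiindex_table()] order.  When `d >= 6r + 3` the
#' space attains the theoretically optimal approximation rate (informational
#' flag `full_rate`).
#'
#' @param mesh a [tet_mesh()].
#' @param d degree (`>= 1`).
#' @param r smoothness order, `0 <= r < d`.
#' @return object of class `spline_space` with fields `mesh`, `d`, `r`, `M`,
#'   `N`, `raw_dim = N * M`, `full_rate`.
#' @export
spline_space <- function(mesh, d, r) {
  if (!inherits(mesh, "tet_mesh")) stop("'mesh' must be a tet_mesh")
  d <- as.integer(d); r <- as.integer(r)
  if (d < 1L) stop("degree 'd' must be >= 1")
  if (r < 0L || r >= d)
    stop("smoothness 'r' must satisfy 0 <= r < d (r = d forces global polynomials)")
  M <- as.integer(choose(d + 3L, 3L))
  structure(list(mesh = mesh, d = d, r = r, M = M, N = nrow(mesh$tets),
                 raw_dim = as.integer(nrow(mesh$tets) * M),
                 full_rate = d >= 6L * r + 3L),
            class = "spline_space")
}

#' @export
print.spline_space <- function(x, ...) {
  cat(sprintf("Spline space S_%d^%d: %d tets x %d basis = %d raw coefficients\n",
              x$d, x$r, x$N, x$M, x$raw_dim))
  invisible(x)
}

#' Sparse spline design matrix
#'
#' Row `i` holds the degree-`d` Bernstein basis values of point `p_i`
#' evaluated in the tetrahedron containing it (all other entries zero), so
#' `B %*% gamma` evaluates the piecewise polynomial at all points.  Points
#' outside the domain get an all-zero row and are flagged.
#'
#' @param space a [spline_space()].
#' @param p n x 3 matrix of points.
#' @param tol containment tolerance passed to [locate_points()].
#' @return list with `B` (sparse n x `raw_dim` matrix), `tet` (locating tet
#'   index per point, `NA` outside), `outside` (logical mask).
#' @export
design_matrix <- function(space, p, tol = NULL) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  p <- as_xyz_matrix(p)
  mesh <- space$mesh; d <- space$d; M <- space$M
  loc <- locate_points(mesh, p, tol)
  inside <- which(!is.na(loc))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  if (length(inside)) {
    P1 <- cbind(1, p)
    for (t in sort(unique(loc[inside]))) {
      rows <- inside[loc[inside] == t]
      b <- P1[rows, , drop = FALSE] %*% t(mesh$bary_mat[, , t])
      Bv <- bernstein_all(d, b)
      ii <- c(ii, rep(rows, times = M))
      jj <- c(jj, rep((t - 1L) * M + seq_len(M), each = length(rows)))
      xx <- c(xx, as.vector(Bv))
    }
  }
  B <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(p), space$raw_dim))
  list(B = B, tet = loc, outside = is.na(loc))
}
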