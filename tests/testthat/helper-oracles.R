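# Independent numerical oracles used across the suite.  Everything here is
# deliberately built from different algorithms than the package internals:
# Gauss-Legendre tensor quadrature via the Duffy transform for integrals,
# direct differentiation of the barycentric monomial form for derivatives,
# and a dense Lagrange-multiplier (KKT) solve for the constrained fit.

unit_corner_tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

regular_tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                     c(0.5, sqrt(3) / 6, sqrt(6) / 3))

# random well-shaped tetrahedron (rejects near-degenerate draws)
random_tet <- function() {
  repeat {
    v <- matrix(stats::runif(12, -1, 1), 4, 3)
    vol <- abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ],
                         v[4, ] - v[1, ])) / 6)
    if (vol > 0.02) return(v)
  }
}

# Gauss-Legendre nodes/weights on [0, 1] (Golub-Welsch)
gauss_legendre01 <- function(n) {
  if (n == 1) return(list(x = 0.5, w = 1))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- (e$values + 1) / 2
  w <- (2 * e$vectors[1, ]^2) / 2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

# quadrature nodes (barycentric) and weights over a tetrahedron via the
# Duffy transform; exact for polynomials up to degree ~2n-3 in each factor
tet_quadrature <- function(v, n = 8) {
  gl <- gauss_legendre01(n)
  g <- expand.grid(u = seq_len(n), v = seq_len(n), w = seq_len(n))
  u <- gl$x[g$u]; vv <- gl$x[g$v]; ww <- gl$x[g$w]
  b2 <- u
  b3 <- vv * (1 - u)
  b4 <- ww * (1 - u) * (1 - vv)
  b1 <- 1 - b2 - b3 - b4
  jac <- (1 - u)^2 * (1 - vv)
  V <- abs(det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])) / 6)
  wq <- 6 * V * gl$w[g$u] * gl$w[g$v] * gl$w[g$w] * jac
  bary <- cbind(b1, b2, b3, b4)
  list(points = bary %*% v, bary = bary, weights = wq)
}

# Hessian of a B-form at points, by direct differentiation of the monomial
# form in barycentric variables chained with the (affine) barycentric
# gradients -- independent of the package's derivative operators.
oracle_hessian <- function(gamma, v, d, p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  tbl <- tpst3d::multiindex_table(d)
  cf <- exp(lgamma(d + 1) - rowSums(lgamma(tbl + 1))) * gamma
  A <- solve(rbind(1, t(v)))      # b = A %*% c(1, p)
  gvec <- A[, 2:4, drop = FALSE]  # gvec[t, ] = grad of b_t
  b <- cbind(1, p) %*% t(A)
  n <- nrow(p)
  H <- array(0, c(n, 3, 3))
  pw <- function(x, e) ifelse(rep(e, length(x)) <= -1, 0, x^pmax(e, 0))
  for (t1 in 1:4) for (t2 in 1:4) {
    # d2/db_t1 db_t2 of each monomial
    acc <- numeric(n)
    for (r in seq_len(nrow(tbl))) {
      e <- tbl[r, ]
      fac <- if (t1 == t2) e[t1] * (e[t1] - 1) else e[t1] * e[t2]
      if (fac == 0) next
      ee <- e; ee[t1] <- ee[t1] - 1L; ee[t2] <- ee[t2] - 1L
      if (any(ee < 0)) next
      term <- rep(cf[r] * fac, n)
      for (m in 1:4) if (ee[m] > 0) term <- term * b[, m]^ee[m]
      acc <- acc + term
    }
    H <- H + outer(acc, outer(gvec[t1, ], gvec[t2, ]))
  }
  H
}

# weighted second-derivative energy of a B-form by quadrature (the Eq-style
# thin-plate integrand), oracle for the penalty matrix
oracle_energy <- function(gamma, v, d, n = 8) {
  q <- tet_quadrature(v, n)
  H <- oracle_hessian(gamma, v, d, q$points)
  integrand <- H[, 1, 1]^2 + H[, 2, 2]^2 + H[, 3, 3]^2 +
    2 * H[, 1, 2]^2 + 2 * H[, 1, 3]^2 + 2 * H[, 2, 3]^2
  sum(q$weights * integrand)
}

# dense KKT (Lagrange multiplier) solve of the constrained penalized LS
# problem: min ||W - B gamma||^2 + rho gamma' P gamma  s.t.  H gamma = 0
kkt_oracle <- function(space, x, w, rho) {
  des <- tpst3d::design_matrix(space, x)
  B <- as.matrix(des$B)[!des$outside, , drop = FALSE]
  w <- w[!des$outside]
  H <- as.matrix(tpst3d::smoothness_constraints(space)$H)
  P <- if (space$d >= 2) as.matrix(tpst3d::assemble_penalty(space))
       else matrix(0, ncol(B), ncol(B))
  nm <- ncol(B); nc <- nrow(H)
  K <- rbind(cbind(crossprod(B) + rho * P, t(H)),
             cbind(H, matrix(0, nc, nc)))
  rhs <- c(crossprod(B, w), numeric(nc))
  sv <- svd(K)
  keep <- sv$d > 1e-10 * sv$d[1]
  sol <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% rhs) / sv$d[keep])
  drop(sol)[seq_len(nm)]
}

# two-tet mesh sharing one face
two_tet_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  tpst3d::tet_mesh(v, rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
}

kuhn_cube_mesh <- function() {
  tpst3d::structured_mesh(c(1, 1, 1), rbind(c(0, 0, 0), c(1, 1, 1)))
}

# mean squared prediction error against the truth on a seeded in-domain grid
mise_on_domain <- function(fit, truth_fn, domain, n_eval = 2000, seed = 99) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  bbox <- tpst3d::domain_bbox(domain)
  pts <- matrix(NA_real_, 0, 3)
  while (nrow(pts) < n_eval) {
    cand <- cbind(stats::runif(3 * n_eval, bbox[1, 1], bbox[2, 1]),
                  stats::runif(3 * n_eval, bbox[1, 2], bbox[2, 2]),
                  stats::runif(3 * n_eval, bbox[1, 3], bbox[2, 3]))
    pts <- rbind(pts, cand[tpst3d::domain_predicate(domain, cand), ,
                           drop = FALSE])
  }
  pts <- pts[seq_len(n_eval), , drop = FALSE]
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  tpst3d::mise(fit, truth_fn, pts)
}
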