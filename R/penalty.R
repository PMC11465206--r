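#' Gram matrix of the Bernstein basis on a tetrahedron
#'
#' Exact integrals `int_T B^d_alpha B^d_beta dV` via the closed-form
#' Bernstein product formula
#' `V_T * prod_m C(alpha_m + beta_m, alpha_m) / (C(2d, d) * C(2d+3, 3))`;
#' symmetric positive definite.
#'
#' @param v 4 x 3 tetrahedron vertex matrix.
#' @param d degree (`>= 0`).
#' @return dense `M x M` matrix, `M = C(d+3, 3)`.
#' @export
bernstein_gram <- function(v, d) {
  met <- tet_metrics(v)
  tbl <- multiindex_table(d)
  M <- nrow(tbl)
  denom <- choose(2 * d, d) * choose(2 * d + 3, 3)
  G <- matrix(0, M, M)
  for (a in seq_len(M)) for (b in a:M) {
    val <- prod(choose(tbl[a, ] + tbl[b, ], tbl[a, ])) / denom
    G[a, b] <- val; G[b, a] <- val
  }
  met[["volume"]] * G
}

#' Roughness-penalty block of one tetrahedron
#'
#' The matrix `P_T` of the weighted second-derivative energy
#' `E(s_T) = int_T s_xx^2 + s_yy^2 + s_zz^2 + 2 s_xy^2 + 2 s_xz^2 + 2 s_yz^2`
#' as a quadratic form in the degree-`d` Bernstein coefficients:
#' `P_T = sum_{|alpha| = 2} w_alpha G_alpha' Gram_{d-2} G_alpha` with
#' multinomial weights `w_alpha = 2! / (a1! a2! a3!)`.  Symmetric positive
#' semidefinite with null space exactly the affine polynomials.
#'
#' @param v 4 x 3 tetrahedron vertex matrix.
#' @param d degree (`>= 2`; second derivatives must exist in the space).
#' @return dense `M x M` matrix.
#' @export
penalty_block <- function(v, d) {
  if (d < 2) stop("the second-derivative penalty requires degree d >= 2")
  Glow <- bernstein_gram(v, d - 2L)
  alphas <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
                  c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  P <- matrix(0, choose(d + 3, 3), choose(d + 3, 3))
  for (s in seq_len(nrow(alphas))) {
    a <- alphas[s, ]
    w <- 2 / prod(factorial(a))
    Ga <- as.matrix(cartesian_derivative_operator(v, d, a))
    P <- P + w * (t(Ga) %*% Glow %*% Ga)
  }
  (P + t(P)) / 2
}

#' Block-diagonal roughness-penalty matrix of a spline space
#'
#' Stacks the per-tetrahedron penalty blocks [penalty_block()] into the
#' sparse block-diagonal matrix `P`, so the total roughness energy of a
#' spline with coefficients `gamma` is `t(gamma) %*% P %*% gamma`.
#'
#' @param space a [spline_space()] with `d >= 2`.
#' @return sparse symmetric `raw_dim x raw_dim` matrix.
#' @export
assemble_penalty <- function(space) {
  mesh <- space$mesh; d <- space$d; M <- space$M
  blocks <- lapply(seq_len(space$N), function(t) {
    penalty_block(mesh$vertices[mesh$tets[t, ], , drop = FALSE], d)
  })
  Matrix::forceSymmetric(Matrix::.bdiag(blocks))
}

#' Roughness energy of a coefficient vector
#'
#' @param gamma raw coefficient vector (length `raw_dim`).
#' @param P penalty matrix from [assemble_penalty()].
#' @return non-negative scalar `t(gamma) P gamma`.
#' @export
energy <- function(gamma, P) {
  if (length(gamma) != nrow(P)) stop("coefficient/penalty shape mismatch")
  max(0, as.numeric(Matrix::crossprod(gamma, P %*% gamma)))
}
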