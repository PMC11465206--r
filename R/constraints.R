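#' C^r smoothness constraint matrix
#'
#' Assembles the sparse matrix `H` whose null space `{gamma : H gamma = 0}`
#' is exactly the set of coefficient vectors representing globally `C^r`
#' piecewise polynomials on the mesh.  For every interior face and every
#' order `m = 0, ..., r` the standard Bernstein coefficient condition is
#' written in a canonical face frame: the shared face vertices are taken in
#' sorted global order `(f1, f2, f3)`, the lower-index incident tetrahedron
#' `T` (frame `<w, f1, f2, f3>`, `w` its off-face vertex) plays the source
#' role, and the higher-index tetrahedron `T~` (frame `<w~, f1, f2, f3>`)
#' the target role:
#'
#' `g~_{m,j,k,l} = sum_{|mu| = m} g_{mu1, j+mu2, k+mu3, l+mu4} B^m_mu(b)`
#'
#' for all `(j, k, l)` with `j + k + l = d - m`, where `b` are the
#' barycentric coordinates of `w~` relative to `T` in frame order.  Each face
#' contributes `sum_{m=0}^{r} C(d-m+2, 2)` rows; a single-tetrahedron mesh
#' yields a 0-row matrix.
#'
#' @param space a [spline_space()].
#' @return list with `H` (sparse matrix, columns = raw coefficients) and
#'   `info` (data frame: face id, order `m`, face multi-index per row).
#' @export
smoothness_constraints <- function(space) {
  mesh <- space$mesh; d <- space$d; r <- space$r; M <- space$M
  faces <- mesh$faces
  rows_per_face <- sum(choose(d - 0:r + 2L, 2L))
  nrow_H <- nrow(faces) * rows_per_face

  # per-order Bernstein tables of degree m (frame barycentrics of w~ wrt T)
  mu_tbl <- lapply(0:r, function(m) multiindex_table(m))

  ii <- vector("list", nrow(faces)); jj <- ii; xx <- ii
  info <- vector("list", nrow(faces))
  row0 <- 0L
  for (f in seq_len(nrow(faces))) {
    tlo <- faces$tet_lo[f]; thi <- faces$tet_hi[f]
    fv <- c(faces$v1[f], faces$v2[f], faces$v3[f])
    frame_lo <- c(faces$opp_lo[f], fv)
    frame_hi <- c(faces$opp_hi[f], fv)
    # perm[t] = stored position in the tet of frame vertex t
    perm_lo <- match(frame_lo, mesh$tets[tlo, ])
    perm_hi <- match(frame_hi, mesh$tets[thi, ])
    # barycentrics of w~ relative to T, re-expressed in frame order
    b_st <- drop(mesh$bary_mat[, , tlo] %*%
                   c(1, mesh$vertices[faces$opp_hi[f], ]))
    b <- b_st[perm_lo]

    fi <- integer(0); fj <- integer(0); fx <- numeric(0)
    fm <- integer(0); fidx <- character(0)
    rr <- 0L
    for (m in 0:r) {
      face_idx <- multiindex_table(d - m)
      face_idx <- face_idx[face_idx[, 1] == 0L, 2:4, drop = FALSE]  # j+k+l = d-m
      mu <- mu_tbl[[m + 1L]]
      Bmu <- vapply(seq_len(nrow(mu)), function(q) {
        bernstein_eval(m, mu[q, ], b)
      }, numeric(1))
      for (s in seq_len(nrow(face_idx))) {
        rr <- rr + 1L
        jkl <- face_idx[s, ]
        # target coefficient in T~: frame index (m, j, k, l)
        tgt_frame <- c(m, jkl)
        tgt_stored <- integer(4L); tgt_stored[perm_hi] <- tgt_frame
        col_t <- (thi - 1L) * M + multiindex_rank(matrix(tgt_stored, 1L), d)
        fi <- c(fi, rr); fj <- c(fj, col_t); fx <- c(fx, 1)
        # source combination in T
        for (q in seq_len(nrow(mu))) {
          src_frame <- c(mu[q, 1], jkl + mu[q, 2:4])
          src_stored <- integer(4L); src_stored[perm_lo] <- src_frame
          col_s <- (tlo - 1L) * M + multiindex_rank(matrix(src_stored, 1L), d)
          fi <- c(fi, rr); fj <- c(fj, col_s); fx <- c(fx, -Bmu[q])
        }
        fm <- c(fm, m); fidx <- c(fidx, paste(jkl, collapse = ","))
      }
    }
    ii[[f]] <- fi + row0; jj[[f]] <- fj; xx[[f]] <- fx
    info[[f]] <- data.frame(face = f, m = fm, face_index = fidx)
    row0 <- row0 + rows_per_face
  }
  H <- Matrix::sparseMatrix(
    i = as.integer(unlist(ii)), j = as.integer(unlist(jj)),
    x = as.numeric(unlist(xx)), dims = c(nrow_H, space$raw_dim))
  list(H = H,
       info = if (length(info)) do.call(rbind, info)
              else data.frame(face = integer(), m = integer(),
                              face_index = character()))
}

#' Orthonormal null-space basis of the smoothness constraints
#'
#' Computes a matrix `Q2` with orthonormal columns spanning the numerical
#' null space of `H`, so any `C^r` spline has `gamma = Q2 %*% theta`.  Two
#' routes are available: a dense SVD of `H` (singular values below
#' `rank_tol * sigma_max` treated as zero), and, for `r = 0`, an exact sparse
#' construction: the `C^0` conditions identify matching face-lattice
#' coefficients across each interior face, so union-find over these pairwise
#' identifications yields disjoint coefficient classes whose normalized
#' indicators form an orthonormal null basis.  `method = "auto"` picks the
#' grouping route for `r = 0`, the SVD otherwise.
#'
#' @param space a [spline_space()].
#' @param constraints optional result of [smoothness_constraints()] (computed
#'   if missing).
#' @param rank_tol relative singular-value tolerance (default `1e-9`).
#' @param method `"auto"`, `"svd"`, or `"group"` (`"group"` requires `r = 0`).
#' @return list with `Q2` (raw_dim x q, orthonormal columns), `q`,
#'   `rank` (of `H`), `rank_tol`, `method`.
#' @export
null_space_basis <- function(space, constraints = NULL, rank_tol = 1e-9,
                             method = c("auto", "svd", "group")) {
  method <- match.arg(method)
  if (method == "auto") method <- if (space$r == 0L) "group" else "svd"
  if (method == "group" && space$r != 0L)
    stop("the domain-point grouping construction applies only to r = 0")
  if (method == "group") return(null_basis_group(space, rank_tol))

  if (is.null(constraints)) constraints <- smoothness_constraints(space)
  H <- constraints$H
  nm <- space$raw_dim
  if (nrow(H) == 0L) {
    return(list(Q2 = Matrix::Diagonal(nm), q = nm, rank = 0L,
                rank_tol = rank_tol, method = method))
  }
  Hd <- as.matrix(H)
  sv <- svd(Hd, nu = 0, nv = nm)
  rank <- sum(sv$d > rank_tol * sv$d[1])
  if (rank >= nm) stop("constraints admit no nontrivial spline space")
  Q2 <- sv$v[, (rank + 1L):nm, drop = FALSE]
  list(Q2 = Q2, q = ncol(Q2), rank = rank, rank_tol = rank_tol,
       method = method)
}

# r = 0: the C^0 conditions identify matching face-lattice coefficients of
# the two tetrahedra incident to each interior face.  Union-find over these
# pairwise identifications gives the exact null space of H; Q2 columns are
# normalized indicators of the classes (orthonormal: disjoint supports).
null_basis_group <- function(space, rank_tol) {
  mesh <- space$mesh; d <- space$d; M <- space$M; N <- space$N
  faces <- mesh$faces
  parent <- seq_len(N * M)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  face_idx <- multiindex_table(d)
  face_idx <- face_idx[face_idx[, 1] == 0L, 2:4, drop = FALSE]
  for (f in seq_len(nrow(faces))) {
    fv <- c(faces$v1[f], faces$v2[f], faces$v3[f])
    perm_lo <- match(c(faces$opp_lo[f], fv), mesh$tets[faces$tet_lo[f], ])
    perm_hi <- match(c(faces$opp_hi[f], fv), mesh$tets[faces$tet_hi[f], ])
    for (s in seq_len(nrow(face_idx))) {
      fr <- c(0L, face_idx[s, ])
      lo_stored <- integer(4L); lo_stored[perm_lo] <- fr
      hi_stored <- integer(4L); hi_stored[perm_hi] <- fr
      a <- (faces$tet_lo[f] - 1L) * M +
        as.integer(multiindex_rank(matrix(lo_stored, 1L), d))
      b <- (faces$tet_hi[f] - 1L) * M +
        as.integer(multiindex_rank(matrix(hi_stored, 1L), d))
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(N * M), find, integer(1))
  grp <- match(root, unique(root))
  q <- max(grp)
  cnt <- tabulate(grp, q)
  Q2 <- Matrix::sparseMatrix(i = seq_len(N * M), j = grp,
                             x = 1 / sqrt(cnt[grp]),
                             dims = c(N * M, q))
  list(Q2 = Q2, q = q, rank = N * M - q, rank_tol = rank_tol,
       method = "group")
}
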