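#' Tetrahedral mesh (triangulation) of a 3D domain
#'
#' Builds a `tet_mesh` object from a vertex table and a tetrahedron index
#' table.  Each tetrahedron is canonically oriented (vertices reordered so the
#' signed volume is positive), per-tetrahedron geometric diagnostics are
#' computed, and the interior-face adjacency needed for smoothness constraints
#' is derived.
#'
#' A valid triangulation requires that any two tetrahedra intersect at most in
#' a common vertex, edge, or triangular face, and that no triangular face is
#' shared by more than two tetrahedra.  Construction only enforces the
#' face-incidence rule; use [validate_triangulation()] for the full geometric
#' report.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z) or a data frame
#'   with columns `x`, `y`, `z`.
#' @param tets integer matrix with 4 columns of 1-based vertex indices.
#' @return An object of class `tet_mesh`: a list with components
#'   `vertices` (V x 3 matrix), `tets` (N x 4 integer matrix, canonical
#'   orientation), `volume`, `longest_edge`, `inradius`, `shape_param`
#'   (per-tet vectors), `mesh_size` (max longest edge), `beta`
#'   (quasi-uniformity ratio `mesh_size / min inradius`), `faces`
#'   (interior-face adjacency, see [face_adjacency()]), `boundary_faces`,
#'   and `bary_mat` (per-tet affine maps to barycentric coordinates).
#' @examples
#' v <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,1))
#' m <- tet_mesh(v, rbind(c(1,2,3,4), c(2,3,4,5)))
#' m$beta
#' @seealso [structured_mesh()], [validate_triangulation()], [locate_points()]
#' @export
tet_mesh <- function(vertices, tets) {
  vertices <- as_xyz_matrix(vertices)
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(tets) != 4L) stop("'tets' must have 4 columns")
  if (any(tets < 1L) || any(tets > nrow(vertices)))
    stop("tetrahedron vertex index out of range [1, ", nrow(vertices), "]")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")

  N <- nrow(tets)
  vol <- numeric(N); led <- numeric(N); inr <- numeric(N)
  bary <- array(NA_real_, c(4L, 4L, N))
  for (t in seq_len(N)) {
    vt <- vertices[tets[t, ], , drop = FALSE]
    sv <- signed_volume(vt)
    if (abs(sv) < .Machine$double.eps * max(1, max(abs(vt)))^3)
      stop("degenerate tetrahedron (coplanar vertices) at index ", t)
    if (sv < 0) { # canonical orientation: positive signed volume
      tets[t, 3:4] <- tets[t, 4:3]
      vt <- vertices[tets[t, ], , drop = FALSE]
    }
    met <- tet_metrics(vt)
    vol[t] <- met[["volume"]]; led[t] <- met[["longest_edge"]]
    inr[t] <- met[["inradius"]]
    bary[, , t] <- solve(rbind(1, t(vt)))
  }

  mesh <- structure(list(
    vertices = vertices, tets = tets,
    volume = vol, longest_edge = led, inradius = inr,
    shape_param = led / inr,
    mesh_size = max(led), beta = max(led) / min(inr),
    bary_mat = bary
  ), class = "tet_mesh")
  adj <- face_adjacency(mesh)
  mesh$faces <- adj$interior
  mesh$boundary_faces <- adj$boundary
  mesh
}

as_xyz_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("x", "y", "z") %in% names(x))) x <- x[, c("x", "y", "z")]
    x <- as.matrix(x)
  }
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) != 3L) stop("expected 3 columns (x, y, z)")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

signed_volume <- function(v) {
  det(rbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])) / 6
}

#' Geometric diagnostics of one tetrahedron
#'
#' Returns the volume, longest edge length, inradius, and shape parameter
#' (longest edge / inradius) of a tetrahedron.  The shape parameter attains
#' its minimum, `2 * sqrt(6)`, exactly for a regular tetrahedron; flatter
#' tetrahedra have larger values.  The inradius is `3 V / A` with `A` the
#' total surface area.
#'
#' @param v 4 x 3 numeric matrix of vertex coordinates.
#' @return Named numeric vector `volume`, `longest_edge`, `inradius`,
#'   `shape_param`.
#' @examples
#' tet_metrics(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)))
#' @export
tet_metrics <- function(v) {
  v <- as_xyz_matrix(v)
  if (nrow(v) != 4L) stop("expected 4 vertices")
  V <- abs(signed_volume(v))
  if (V < .Machine$double.eps * max(1, max(abs(v)))^3)
    stop("degenerate tetrahedron: coplanar vertices")
  pairs <- utils::combn(4L, 2L)
  edges <- sqrt(colSums((t(v[pairs[1, ], ]) - t(v[pairs[2, ], ]))^2))
  tri_area <- function(a, b, c) {
    u <- b - a; w <- c - a
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    sqrt(sum(cr^2)) / 2
  }
  A <- tri_area(v[2, ], v[3, ], v[4, ]) + tri_area(v[1, ], v[3, ], v[4, ]) +
       tri_area(v[1, ], v[2, ], v[4, ]) + tri_area(v[1, ], v[2, ], v[3, ])
  rho <- 3 * V / A
  c(volume = V, longest_edge = max(edges), inradius = rho,
    shape_param = max(edges) / rho)
}

#' Barycentric coordinates relative to a tetrahedron
#'
#' Solves the 4 x 4 affine system expressing each point as a weighted
#' combination of the four tetrahedron vertices with weights summing to one.
#' Components are negative for points outside the tetrahedron.
#'
#' @param v 4 x 3 matrix of tetrahedron vertices.
#' @param p points: length-3 vector or n x 3 matrix.
#' @return n x 4 matrix of barycentric coordinates (rows sum to 1).
#' @examples
#' v <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))
#' barycentric_coords(v, c(0.25, 0.25, 0.25))
#' @export
barycentric_coords <- function(v, p) {
  v <- as_xyz_matrix(v)
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  p <- as_xyz_matrix(p)
  A <- rbind(1, t(v))
  if (abs(det(A)) < .Machine$double.eps * max(1, max(abs(v)))^3)
    stop("degenerate tetrahedron: coplanar vertices")
  t(solve(A, rbind(1, t(p))))
}

#' Interior/boundary face adjacency of a triangulation
#'
#' Enumerates the triangular faces of a mesh.  Each interior face is reported
#' once with its two incident tetrahedra (`tet_lo < tet_hi`), the shared
#' vertex triple in sorted global order, and the "opposite" vertex of each
#' incident tetrahedron (its vertex not on the face).  Satisfies the face
#' count identity `4 N = 2 F_int + F_bdy`.
#'
#' @param mesh a `tet_mesh` (or a list with `vertices` and `tets`).
#' @return list with `interior` and `boundary` data frames.
#' @export
face_adjacency <- function(mesh) {
  tets <- mesh$tets
  N <- nrow(tets)
  # 4 faces per tet: face f omits local vertex f
  omit <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  tet_id <- rep(seq_len(N), each = 4L)
  opp_local <- rep(1:4, times = N)
  fv <- matrix(0L, 4L * N, 3L)
  for (f in 1:4) {
    rows <- which(opp_local == f)
    tri <- tets[tet_id[rows], omit[f, ], drop = FALSE]
    fv[rows, ] <- t(apply(tri, 1L, sort))
  }
  key <- paste(fv[, 1], fv[, 2], fv[, 3], sep = "_")
  cnt <- table(key)
  if (any(cnt > 2L))
    stop("invalid triangulation: a face is shared by more than 2 tetrahedra")
  ord <- order(key, tet_id)
  key_o <- key[ord]
  first <- !duplicated(key_o)
  idx_first <- which(first)
  runlen <- diff(c(idx_first, length(key_o) + 1L))
  int_sel <- runlen == 2L
  i1 <- ord[idx_first[int_sel]]
  i2 <- ord[idx_first[int_sel] + 1L]
  opp_vertex <- tets[cbind(tet_id, opp_local)]
  interior <- data.frame(
    tet_lo = tet_id[i1], tet_hi = tet_id[i2],
    v1 = fv[i1, 1], v2 = fv[i1, 2], v3 = fv[i1, 3],
    opp_lo = opp_vertex[i1], opp_hi = opp_vertex[i2]
  )
  ib <- ord[idx_first[!int_sel]]
  boundary <- data.frame(tet = tet_id[ib],
                         v1 = fv[ib, 1], v2 = fv[ib, 2], v3 = fv[ib, 3],
                         opp = opp_vertex[ib])
  list(interior = interior, boundary = boundary)
}

#' Validity report for a triangulation
#'
#' Checks that the mesh is a proper triangulation: no triangular face is
#' incident to more than two tetrahedra, and no two tetrahedra have
#' overlapping interiors (tetrahedra may meet only at a shared vertex, edge,
#' or face).  Interior overlap is detected by testing a fixed set of interior
#' sample points of each tetrahedron for strict containment in the other,
#' restricted to bounding-box-intersecting pairs; exact geometric predicates
#' are deliberately not attempted.
#'
#' @param mesh a `tet_mesh`.
#' @return A data frame report with columns `type` (`"face_incidence"` or
#'   `"interior_overlap"`), `tet_a`, `tet_b`.  Zero rows means valid; the
#'   logical attribute `"valid"` carries the same information.
#' @export
validate_triangulation <- function(mesh) {
  report <- data.frame(type = character(), tet_a = integer(), tet_b = integer())
  tets <- mesh$tets; V <- mesh$vertices; N <- nrow(tets)

  omit <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  keys <- character(4L * N); tid <- rep(seq_len(N), each = 4L)
  k <- 1L
  for (t in seq_len(N)) for (f in 1:4) {
    keys[k] <- paste(sort(tets[t, omit[f, ]]), collapse = "_"); k <- k + 1L
  }
  cnt <- table(keys)
  bad <- names(cnt)[cnt > 2L]
  for (b in bad) {
    tt <- sort(unique(tid[keys == b]))
    report <- rbind(report, data.frame(type = "face_incidence",
                                       tet_a = tt[1], tet_b = tt[2]))
  }

  # fixed interior sample points in barycentric coordinates (deterministic)
  samp <- rbind(
    c(0.25, 0.25, 0.25, 0.25),
    diag(4) * 0.8 + 0.05,                        # near-vertex points
    c(0.4, 0.4, 0.1, 0.1), c(0.4, 0.1, 0.4, 0.1), c(0.4, 0.1, 0.1, 0.4),
    c(0.1, 0.4, 0.4, 0.1), c(0.1, 0.4, 0.1, 0.4), c(0.1, 0.1, 0.4, 0.4),
    c(0.55, 0.15, 0.15, 0.15), c(0.15, 0.55, 0.15, 0.15),
    c(0.15, 0.15, 0.55, 0.15), c(0.15, 0.15, 0.15, 0.55)
  )
  lo <- matrix(0, N, 3L); hi <- matrix(0, N, 3L)
  pts <- vector("list", N)
  for (t in seq_len(N)) {
    vt <- V[tets[t, ], , drop = FALSE]
    lo[t, ] <- apply(vt, 2, min); hi[t, ] <- apply(vt, 2, max)
    pts[[t]] <- samp %*% vt
  }
  eps <- 1e-9 * max(mesh$longest_edge)
  for (a in seq_len(N)) {
    if (a == N) break
    for (b in (a + 1L):N) {
      if (any(lo[b, ] > hi[a, ] + eps) || any(lo[a, ] > hi[b, ] + eps)) next
      overlap <- FALSE
      ba <- barycentric_coords(V[tets[b, ], ], pts[[a]])
      if (any(apply(ba, 1, min) > 1e-9)) overlap <- TRUE
      if (!overlap) {
        bb <- barycentric_coords(V[tets[a, ], ], pts[[b]])
        if (any(apply(bb, 1, min) > 1e-9)) overlap <- TRUE
      }
      if (overlap)
        report <- rbind(report, data.frame(type = "interior_overlap",
                                           tet_a = a, tet_b = b))
    }
  }
  attr(report, "valid") <- nrow(report) == 0L
  report
}

#' Locate points in a triangulation
#'
#' Assigns each query point to the tetrahedron containing it, or `NA` for
#' points outside the domain.  A point is inside a tetrahedron when all four
#' barycentric coordinates are `>= -tol`; points on shared faces, edges or
#' vertices are resolved deterministically to the lowest tetrahedron index.
#'
#' @param mesh a `tet_mesh`.
#' @param p n x 3 matrix (or length-3 vector) of query points.
#' @param tol non-negative containment tolerance on barycentric coordinates;
#'   default `1e-10 * mesh_size`.
#' @return integer vector of tetrahedron indices (`NA` = outside).
#' @export
locate_points <- function(mesh, p, tol = NULL) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  p <- as_xyz_matrix(p)
  if (is.null(tol)) tol <- 1e-10 * mesh$mesh_size
  if (tol < 0) stop("'tol' must be non-negative")
  n <- nrow(p); N <- nrow(mesh$tets)
  res <- rep(NA_integer_, n)
  unassigned <- rep(TRUE, n)
  P1 <- cbind(1, p)
  for (t in seq_len(N)) {
    cand <- which(unassigned)
    if (!length(cand)) break
    vt <- mesh$vertices[mesh$tets[t, ], , drop = FALSE]
    lo <- apply(vt, 2, min) - tol * (1 + mesh$longest_edge[t])
    hi <- apply(vt, 2, max) + tol * (1 + mesh$longest_edge[t])
    inbox <- cand[p[cand, 1] >= lo[1] & p[cand, 1] <= hi[1] &
                  p[cand, 2] >= lo[2] & p[cand, 2] <= hi[2] &
                  p[cand, 3] >= lo[3] & p[cand, 3] <= hi[3]]
    if (!length(inbox)) next
    b <- P1[inbox, , drop = FALSE] %*% t(mesh$bary_mat[, , t])
    inside <- rowSums(b >= -tol) == 4L
    hit <- inbox[inside]
    res[hit] <- t
    unassigned[hit] <- FALSE
  }
  res
}

#' Suggested number of tetrahedra for a sample size
#'
#' Mesh-fineness heuristic `N = floor(c1 * n^gamma * log(n) + c2)` tying the
#' triangulation resolution to the sample size; monotone non-decreasing in
#' `n`.
#'
#' @param n sample size (`>= 2`).
#' @param gamma growth exponent in `(0, 1)`.
#' @param c1,c2 non-negative tuning constants.
#' @return integer suggested number of tetrahedra.
#' @examples
#' suggest_mesh_size(20000, gamma = 0.4, c1 = 0.5, c2 = 10)
#' @export
suggest_mesh_size <- function(n, gamma, c1 = 1, c2 = 0) {
  if (n < 2) stop("'n' must be >= 2")
  if (gamma <= 0 || gamma >= 1) stop("'gamma' must lie in (0, 1)")
  if (c1 < 0) stop("'c1' must be non-negative")
  as.integer(floor(c1 * n^gamma * log(n) + c2))
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("Tetrahedral mesh:", nrow(x$tets), "tets,", nrow(x$vertices),
      "vertices\n")
  cat(sprintf("  mesh size |D| = %.4g, quasi-uniformity beta = %.4g\n",
              x$mesh_size, x$beta))
  cat(sprintf("  interior faces: %d, boundary faces: %d\n",
              nrow(x$faces), nrow(x$boundary_faces)))
  invisible(x)
}
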