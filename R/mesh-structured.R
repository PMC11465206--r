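#' Structured in-domain tetrahedral mesh (Kuhn split)
#'
#' Generates a tetrahedral mesh of (a subset of) an axis-aligned box by
#' splitting every cell of a regular `nx x ny x nz` grid into 6 tetrahedra
#' along the main diagonal (the Kuhn/Freudenthal split, which is conforming
#' across neighbouring cells).  A tetrahedron is kept if and only if its
#' centroid satisfies the `inside` predicate, so non-convex and holed domains
#' are meshed by their indicator function.
#'
#' @param grid integer vector `c(nx, ny, nz)`, each `>= 1`.
#' @param bbox 2 x 3 matrix: first row lower corner, second row upper corner.
#' @param inside predicate: a function taking an n x 3 matrix of points and
#'   returning a logical vector, or a `domain_spec` (see [domain_spec()]).
#'   Default keeps the full box.
#' @return a [tet_mesh()] containing only the kept tetrahedra (unused grid
#'   vertices are dropped).
#' @examples
#' m <- structured_mesh(c(1, 1, 1), rbind(c(0, 0, 0), c(1, 1, 1)))
#' nrow(m$tets)  # 6
#' @export
structured_mesh <- function(grid, bbox, inside = NULL) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 1L)) stop("'grid' must be 3 integers >= 1")
  bbox <- as.matrix(bbox)
  if (any(bbox[2, ] <= bbox[1, ])) stop("'bbox' upper corner must exceed lower")
  if (inherits(inside, "domain_spec")) {
    spec <- inside
    inside <- function(p) domain_predicate(spec, p)
  }
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  xs <- seq(bbox[1, 1], bbox[2, 1], length.out = nx + 1L)
  ys <- seq(bbox[1, 2], bbox[2, 2], length.out = ny + 1L)
  zs <- seq(bbox[1, 3], bbox[2, 3], length.out = nz + 1L)
  vid <- function(i, j, k) i + (nx + 1L) * (j + (ny + 1L) * k) + 1L
  verts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))

  # 6 Kuhn tets per cell: paths 000 -> 111 adding one axis at a time
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cells <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  ntet <- nrow(cells) * 6L
  tets <- matrix(0L, ntet, 4L)
  row <- 1L
  for (c_ in seq_len(nrow(cells))) {
    ijk <- as.integer(cells[c_, ])
    for (pp in 1:6) {
      off <- c(0L, 0L, 0L)
      ids <- integer(4L)
      ids[1] <- vid(ijk[1], ijk[2], ijk[3])
      for (s in 1:3) {
        off[perms[pp, s]] <- 1L
        ids[s + 1L] <- vid(ijk[1] + off[1], ijk[2] + off[2], ijk[3] + off[3])
      }
      tets[row, ] <- ids
      row <- row + 1L
    }
  }
  if (!is.null(inside)) {
    cen <- (verts[tets[, 1], ] + verts[tets[, 2], ] +
            verts[tets[, 3], ] + verts[tets[, 4], ]) / 4
    keep <- as.logical(inside(cen))
    if (anyNA(keep)) stop("'inside' returned NA")
    tets <- tets[keep, , drop = FALSE]
  }
  if (nrow(tets) == 0L)
    stop("empty mesh: no tetrahedron centroid satisfies 'inside'")
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4L)
  tet_mesh(verts[used, , drop = FALSE], tets)
}
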