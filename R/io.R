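#' Read a tetrahedral mesh from file
#'
#' Supports the TetGen dialect (a `.node` / `.ele` file pair: first line a
#' count, then one vertex or tetrahedron per line with a leading index; the
#' file's own first-index convention, 0 or 1, is auto-detected) and a JSON
#' dialect `{"vertices": [[x,y,z],...], "tetrahedra": [[i,j,k,l],...]}` with
#' 0-based indices.
#'
#' @param path for `"tetgen"`, the basename or the `.node` path (the `.ele`
#'   file must sit next to it); for `"json"`, the JSON file.
#' @param dialect `"tetgen"` or `"json"` (default: guessed from the
#'   extension).
#' @return a [tet_mesh()].
#' @export
read_mesh <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
               else "tetgen"
  }
  dialect <- match.arg(dialect, c("tetgen", "json"))
  if (dialect == "json") {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    if (is.null(obj$vertices) || is.null(obj$tetrahedra))
      stop("JSON mesh must contain 'vertices' and 'tetrahedra'")
    verts <- matrix(as.numeric(obj$vertices), ncol = 3)
    tets <- matrix(as.integer(obj$tetrahedra), ncol = 4) + 1L
    if (any(tets < 1L) || any(tets > nrow(verts)))
      stop("tetrahedron index out of range in ", path)
    return(tet_mesh(verts, tets))
  }
  base <- sub("\\.node$", "", path)
  node_path <- paste0(base, ".node"); ele_path <- paste0(base, ".ele")
  nodes <- read_tetgen_table(node_path, 3L)
  eles <- read_tetgen_table(ele_path, 4L)
  idx0 <- min(nodes$index)
  if (!idx0 %in% c(0L, 1L))
    stop("cannot detect index base of ", node_path, " (first index ", idx0, ")")
  tets <- matrix(as.integer(eles$values), ncol = 4L) - idx0 + 1L
  if (any(tets < 1L) || any(tets > nrow(nodes$values)))
    stop("tetrahedron vertex index out of range in ", ele_path)
  # vertices may be listed in any order: sort by declared index
  ordv <- order(nodes$index)
  verts <- matrix(as.numeric(nodes$values), ncol = 3L)[ordv, , drop = FALSE]
  tet_mesh(verts, tets)
}

read_tetgen_table <- function(path, ncol_body) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  head_n <- as.integer(strsplit(lines[1], "\\s+")[[1]][1])
  if (is.na(head_n) || head_n < 1)
    stop("malformed count on line 1 of ", path)
  if (length(lines) < head_n + 1L)
    stop("expected ", head_n, " records in ", path, ", found ",
         length(lines) - 1L)
  idx <- integer(head_n)
  vals <- matrix(NA_real_, head_n, ncol_body)
  for (r in seq_len(head_n)) {
    fields <- as.numeric(strsplit(lines[r + 1L], "\\s+")[[1]])
    if (length(fields) < ncol_body + 1L || anyNA(fields[1:(ncol_body + 1L)]))
      stop("malformed record on line ", r + 1L, " of ", path)
    idx[r] <- as.integer(fields[1])
    vals[r, ] <- fields[2:(ncol_body + 1L)]
  }
  list(index = idx, values = vals)
}

#' Write a mesh to file
#'
#' The JSON writer always emits 0-based indices; the TetGen writer emits
#' 1-based `.node`/`.ele` files.
#'
#' @param mesh a [tet_mesh()].
#' @param path output path (basename for TetGen).
#' @param dialect `"json"` or `"tetgen"`.
#' @return the path(s) written, invisibly.
#' @export
write_mesh <- function(mesh, path, dialect = c("json", "tetgen")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    obj <- list(vertices = unname(mesh$vertices),
                tetrahedra = unname(mesh$tets - 1L))
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
    return(invisible(path))
  }
  base <- sub("\\.node$", "", path)
  nv <- nrow(mesh$vertices)
  node_lines <- c(sprintf("%d 3 0 0", nv),
                  sprintf("%d %.17g %.17g %.17g", seq_len(nv),
                          mesh$vertices[, 1], mesh$vertices[, 2],
                          mesh$vertices[, 3]))
  writeLines(node_lines, paste0(base, ".node"))
  nt <- nrow(mesh$tets)
  ele_lines <- c(sprintf("%d 4 0", nt),
                 sprintf("%d %d %d %d %d", seq_len(nt), mesh$tets[, 1],
                         mesh$tets[, 2], mesh$tets[, 3], mesh$tets[, 4]))
  writeLines(ele_lines, paste0(base, ".ele"))
  invisible(c(paste0(base, ".node"), paste0(base, ".ele")))
}

#' Read / write point clouds as CSV
#'
#' CSV with header columns `x,y,z` and optionally `w` (response), `m`
#' (truth) and `sigma` (noise scale); extra columns are preserved in the
#' `extra` element.  Numbers are written with 17 significant digits so a
#' write/read round trip reproduces doubles exactly.
#'
#' @param path CSV path.
#' @param require_w error if the response column is absent.
#' @return a `point_cloud` list (`x`, `w`, `m`, `sigma`, `n`, `extra`).
#' @export
read_point_cloud <- function(path, require_w = TRUE) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("point-cloud CSV must have columns x, y, z")
  if (require_w && !"w" %in% names(df))
    stop("point-cloud CSV lacks the response column 'w'")
  known <- c("x", "y", "z", "w", "m", "sigma")
  structure(list(
    x = as.matrix(df[, need]),
    w = if ("w" %in% names(df)) df$w else NULL,
    m = if ("m" %in% names(df)) df$m else NULL,
    sigma = if ("sigma" %in% names(df)) df$sigma else NULL,
    n = nrow(df),
    extra = df[, setdiff(names(df), known), drop = FALSE]
  ), class = "point_cloud")
}

#' @rdname read_point_cloud
#' @param cloud a `point_cloud` (or list with `x` and optionally `w`, `m`,
#'   `sigma`).
#' @export
write_point_cloud <- function(cloud, path) {
  df <- data.frame(x = cloud$x[, 1], y = cloud$x[, 2], z = cloud$x[, 3])
  for (col in c("w", "m", "sigma"))
    if (!is.null(cloud[[col]])) df[[col]] <- cloud[[col]]
  if (!is.null(cloud$extra) && ncol(cloud$extra)) df <- cbind(df, cloud$extra)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Point cloud from a masked NIfTI volume
#'
#' Turns a 3D volume into a point cloud: one point per in-mask voxel at its
#' world-coordinate center (through the image's affine), with the voxel
#' intensity as response.  The grid metadata is retained so predictions can
#' be written back as a volume with [point_cloud_volume()].
#'
#' @param image path to a `.nii`/`.nii.gz` file, or an `RNifti` image.
#' @param mask same-shaped volume/path (nonzero = inside), or a numeric
#'   threshold applied to the image intensities.
#' @return a `point_cloud` with an extra `grid` element (`dim`, `affine`,
#'   `voxel_index` of each point).
#' @export
nifti_point_cloud <- function(image, mask = NULL) {
  img <- if (is.character(image)) RNifti::readNifti(image) else image
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume")
  if (is.null(mask)) {
    msk <- array(TRUE, dim(arr))
  } else if (is.numeric(mask) && length(mask) == 1L) {
    msk <- arr > mask
  } else {
    marr <- as.array(if (is.character(mask)) RNifti::readNifti(mask) else mask)
    if (!identical(dim(marr), dim(arr)))
      stop("mask shape ", paste(dim(marr), collapse = "x"),
           " does not match image shape ", paste(dim(arr), collapse = "x"))
    msk <- marr != 0
  }
  idx <- which(msk, arr.ind = TRUE)
  aff <- RNifti::xform(img)
  # voxel (1-based) -> world: affine acts on 0-based voxel indices
  world <- cbind(idx - 1L, 1) %*% t(aff)
  structure(list(x = world[, 1:3, drop = FALSE], w = arr[msk],
                 n = nrow(idx),
                 grid = list(dim = dim(arr), affine = aff,
                             voxel_index = idx)),
            class = "point_cloud")
}

#' Write predicted values back into a volume
#'
#' @param cloud a `point_cloud` from [nifti_point_cloud()] (carries the grid
#'   metadata).
#' @param values per-point values (e.g. TPST predictions).
#' @param background fill value for out-of-mask voxels (default `NA`).
#' @return a 3D array of the original volume shape.
#' @export
point_cloud_volume <- function(cloud, values, background = NA_real_) {
  if (is.null(cloud$grid)) stop("cloud carries no grid metadata")
  if (length(values) != cloud$n) stop("length mismatch")
  arr <- array(background, cloud$grid$dim)
  arr[cloud$grid$voxel_index] <- values
  arr
}

# ---- model archive ---------------------------------------------------------

# md5 of the canonical textual mesh serialization (vertex strings + indices)
mesh_content_hash <- function(mesh_obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(as.vector(mesh_obj$vertices),
               as.character(as.vector(mesh_obj$tetrahedra))), tmp)
  unname(tools::md5sum(tmp))
}

#' Save / load a fitted TPST model archive
#'
#' The archive (JSON) stores the reduced coefficients `theta`, the embedded
#' mesh, degree, smoothness, penalty parameter, ridge, the coefficient
#' ordering tag, and provenance; the null-space basis `Q2` is rebuilt
#' deterministically on load from (mesh, d, r, rank_tol), so reloaded models
#' give identical predictions.  This is the numerosity-reduced
#' representation of the fitted point cloud: `q` numbers instead of `n`
#' observations (the archive records the compression ratio `n / q`).
#'
#' @param fit a [tpst()] fit.
#' @param path archive path (`.json`).
#' @return `save_tpst`: the path, invisibly.  `load_tpst`: an object of
#'   class `tpst` usable with [predict.tpst()].
#' @export
save_tpst <- function(fit, path) {
  mesh <- fit$space$mesh
  # doubles as %.17g strings: a write/read round trip is then bit-exact
  mesh_obj <- list(vertices = matrix(sprintf("%.17g", mesh$vertices),
                                     ncol = 3),
                   tetrahedra = unname(mesh$tets - 1L))
  hash <- mesh_content_hash(mesh_obj)
  obj <- list(
    format = "tpst-archive", version = 1L,
    ordering = "lexicographic_i_desc",
    d = fit$space$d, r = fit$space$r,
    rho = fit$rho, ridge_used = fit$ridge_used,
    rank_tol = fit$rank_tol, null_method = fit$null_method,
    q = fit$q, raw_dim = fit$raw_dim, n_used = fit$n_used,
    compression_ratio = fit$n_used / fit$q,
    mesh_hash = hash, mesh = mesh_obj,
    theta = sprintf("%.17g", fit$theta),
    provenance = list(package = "tpst3d",
                      r_version = as.character(getRversion()),
                      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_tpst
#' @export
load_tpst <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(obj$format, "tpst-archive"))
    stop("not a TPST model archive: ", path)
  if (!identical(obj$ordering, "lexicographic_i_desc"))
    stop("unsupported coefficient ordering tag: ", obj$ordering)
  mesh_obj <- list(vertices = matrix(as.character(obj$mesh$vertices),
                                     ncol = 3),
                   tetrahedra = matrix(as.integer(obj$mesh$tetrahedra),
                                       ncol = 4))
  hash <- mesh_content_hash(mesh_obj)
  if (!identical(hash, obj$mesh_hash))
    stop("mesh content hash mismatch: archive tampered or corrupted")
  mesh <- tet_mesh(matrix(as.numeric(mesh_obj$vertices), ncol = 3),
                   mesh_obj$tetrahedra + 1L)
  space <- spline_space(mesh, obj$d, obj$r)
  nb <- null_space_basis(space, rank_tol = obj$rank_tol,
                         method = obj$null_method)
  if (nb$q != obj$q)
    stop("null-space dimension mismatch on reload: archive says ", obj$q,
         ", rebuilt ", nb$q)
  theta <- as.numeric(obj$theta)
  if (length(theta) != nb$q) stop("coefficient count mismatch in archive")
  structure(list(
    space = space, rho = obj$rho, theta = theta,
    gamma = as.numeric(nb$Q2 %*% theta),
    q = nb$q, raw_dim = space$raw_dim, n_used = obj$n_used,
    rank_tol = obj$rank_tol, null_method = nb$method,
    ridge_used = obj$ridge_used, fitted = NULL
  ), class = "tpst")
}
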