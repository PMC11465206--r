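#' Built-in complex 3D domains
#'
#' Closed-form membership domains used by the synthetic-data generators and
#' the structured mesh generator.
#'
#' `"unit_box"`: the axis-aligned box `bbox`.
#'
#' `"box_with_hole"`: an outer box with an inner box-shaped hole strictly
#' inside it; a point belongs to the domain when it lies inside the outer box
#' and outside the open hole.  Defaults: outer box `3 x 1 x 1` at the origin
#' corner, hole `1 x 0.4 x 0.4` centered.
#'
#' `"horseshoe3d"`: an annular C extruded in `z`.  A point `(x, y, z)` with
#' cylindrical radius `rho = sqrt(x^2 + y^2)` and angle `theta = atan2(y, x)`
#' belongs to the arc when `z` is within the thickness, `rin <= rho <= rout`,
#' `|theta| >= gap` (the wedge `|theta| < gap` is the opening of the C) and
#' `x <= 0` when arms are present.  With `arm_length > 0` two straight
#' prismatic arms `0 <= x <= arm_length`, `rin <= |y| <= rout` prolong the
#' half-annulus, leaving the slab between them (`|y| < rin`, `x > 0`) as the
#' horseshoe gap.  Defaults: `rin = 0.5`, `rout = 1`, `gap = 15` degrees,
#' `thickness = 0.5`, `arm_length = 1`.
#'
#' @param name one of `"unit_box"`, `"box_with_hole"`, `"horseshoe3d"`.
#' @param ... geometry overrides: for `box_with_hole`, `outer` (2 x 3 bbox
#'   matrix) and `hole` (2 x 3 bbox matrix); for `horseshoe3d`, `rin`,
#'   `rout`, `gap_deg`, `thickness`, `arm_length`; for `unit_box`, `bbox`.
#' @return object of class `domain_spec`.
#' @examples
#' dom <- domain_spec("box_with_hole")
#' domain_predicate(dom, c(1.5, 0.5, 0.5))  # center of the hole: FALSE
#' @export
domain_spec <- function(name = c("box_with_hole", "horseshoe3d", "unit_box"),
                        ...) {
  name <- match.arg(name)
  over <- list(...)
  spec <- switch(name,
    unit_box = list(bbox = rbind(c(0, 0, 0), c(1, 1, 1))),
    box_with_hole = list(
      outer = rbind(c(0, 0, 0), c(3, 1, 1)),
      hole = rbind(c(1, 0.3, 0.3), c(2, 0.7, 0.7))
    ),
    horseshoe3d = list(rin = 0.5, rout = 1, gap_deg = 15, thickness = 0.5,
                       arm_length = 1)
  )
  for (nm in names(over)) {
    if (!nm %in% names(spec)) stop("unknown geometry parameter: ", nm)
    spec[[nm]] <- over[[nm]]
  }
  spec$name <- name
  validate_domain_spec(spec)
  structure(spec, class = "domain_spec")
}

validate_domain_spec <- function(spec) {
  if (spec$name == "box_with_hole") {
    if (any(spec$hole[1, ] <= spec$outer[1, ]) ||
        any(spec$hole[2, ] >= spec$outer[2, ]))
      stop("hole must lie strictly inside the outer box")
  }
  if (spec$name == "horseshoe3d") {
    if (spec$rin <= 0 || spec$rout <= spec$rin)
      stop("need 0 < rin < rout")
    if (spec$gap_deg <= 0 || spec$gap_deg >= 90)
      stop("gap half-angle must be in (0, 90) degrees (non-empty gap)")
    if (spec$thickness <= 0) stop("thickness must be positive")
    if (spec$arm_length < 0) stop("arm_length must be non-negative")
  }
  invisible(spec)
}

#' Domain membership test
#'
#' @param spec a [domain_spec()].
#' @param p length-3 vector or n x 3 matrix of points.
#' @return logical vector.
#' @export
domain_predicate <- function(spec, p) {
  if (!inherits(spec, "domain_spec")) stop("'spec' must be a domain_spec")
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  p <- as_xyz_matrix(p)
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  switch(spec$name,
    unit_box = {
      b <- spec$bbox
      x >= b[1, 1] & x <= b[2, 1] & y >= b[1, 2] & y <= b[2, 2] &
        z >= b[1, 3] & z <= b[2, 3]
    },
    box_with_hole = {
      o <- spec$outer; h <- spec$hole
      in_outer <- x >= o[1, 1] & x <= o[2, 1] & y >= o[1, 2] & y <= o[2, 2] &
        z >= o[1, 3] & z <= o[2, 3]
      in_hole <- x > h[1, 1] & x < h[2, 1] & y > h[1, 2] & y < h[2, 2] &
        z > h[1, 3] & z < h[2, 3]
      in_outer & !in_hole
    },
    horseshoe3d = {
      rho <- sqrt(x^2 + y^2)
      theta <- atan2(y, x)
      gap <- spec$gap_deg * pi / 180
      in_z <- z >= 0 & z <= spec$thickness
      ann <- rho >= spec$rin & rho <= spec$rout & abs(theta) >= gap
      if (spec$arm_length > 0) {
        arc <- ann & x <= 0
        arm <- x >= 0 & x <= spec$arm_length &
          abs(y) >= spec$rin & abs(y) <= spec$rout
        in_z & (arc | arm)
      } else {
        in_z & ann
      }
    })
}

#' Bounding box of a domain
#'
#' @param spec a [domain_spec()].
#' @return 2 x 3 matrix: lower and upper corners.
#' @export
domain_bbox <- function(spec) {
  switch(spec$name,
    unit_box = spec$bbox,
    box_with_hole = spec$outer,
    horseshoe3d = rbind(
      c(-spec$rout, -spec$rout, 0),
      c(max(spec$arm_length, spec$rout), spec$rout, spec$thickness))
  )
}
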