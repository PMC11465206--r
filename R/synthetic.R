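#' Smooth test signals
#'
#' Four fixed smooth (C-infinity on the bounding box) test functions used by
#' the simulation studies.  Coordinates are affinely rescaled to `[0, 1]`
#' over the supplied bounding box, so each signal adapts to any domain:
#'
#' * `m1(p) = sin(pi xt) + cos(pi yt) + zt^2` — low-frequency,
#' * `m2(p) = sin(3 pi xt) * cos(3 pi yt) * sin(2 pi zt)` — high-frequency,
#' * `m3(p) = cos(pi xt) * sin(pi yt) + zt` — low-frequency variant,
#' * `m4(p) = sin(2 pi xt) * cos(2 pi yt) + sin(2 pi zt) * cos(pi xt)` —
#'   high-frequency variant,
#'
#' where `xt, yt, zt` are the rescaled coordinates.  `m2` (resp. `m4`) has
#' strictly larger total variation than `m1` (resp. `m3`), emulating signals
#' with different degrees of variation.
#'
#' @param name `"m1"`, `"m2"`, `"m3"`, or `"m4"`.
#' @param p length-3 vector or n x 3 matrix of points.
#' @param bbox 2 x 3 bounding box used for rescaling (e.g.
#'   [domain_bbox()]); default the unit box.
#' @return numeric vector of signal values.
#' @export
test_function <- function(name, p, bbox = rbind(c(0, 0, 0), c(1, 1, 1))) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  p <- as_xyz_matrix(p)
  bbox <- as.matrix(bbox)
  xt <- (p[, 1] - bbox[1, 1]) / (bbox[2, 1] - bbox[1, 1])
  yt <- (p[, 2] - bbox[1, 2]) / (bbox[2, 2] - bbox[1, 2])
  zt <- (p[, 3] - bbox[1, 3]) / (bbox[2, 3] - bbox[1, 3])
  switch(name,
    m1 = sin(pi * xt) + cos(pi * yt) + zt^2,
    m2 = sin(3 * pi * xt) * cos(3 * pi * yt) * sin(2 * pi * zt),
    m3 = cos(pi * xt) * sin(pi * yt) + zt,
    m4 = sin(2 * pi * xt) * cos(2 * pi * yt) + sin(2 * pi * zt) * cos(pi * xt),
    stop("unknown test function: ", name))
}

#' Noise level from a peak signal-to-noise ratio
#'
#' Inverts `PSNR = 20 log10(max|m| / sigma)`: `sigma = m_max / 10^(PSNR/20)`.
#'
#' @param m_max peak absolute signal value (`> 0`).
#' @param psnr peak signal-to-noise ratio in dB (finite).
#' @return noise standard deviation `sigma`.
#' @examples
#' sigma_from_psnr(1, 20)  # 0.1
#' @export
sigma_from_psnr <- function(m_max, psnr) {
  if (!is.finite(psnr)) stop("'psnr' must be finite")
  if (m_max <= 0) stop("'m_max' must be positive")
  m_max / 10^(psnr / 20)
}

#' Simulate a noisy point cloud on a complex domain
#'
#' Generates the simulation designs used throughout the package's studies:
#' uniform random or voxel-grid point locations restricted to a
#' [domain_spec()], a smooth truth signal, Gaussian noise calibrated either
#' by an explicit `sigma` (scalar or function of location, for
#' heteroscedastic designs) or by a peak signal-to-noise ratio, and three
#' missing-data schemes:
#'
#' * `"none"` — complete data;
#' * `"random"` — exactly `floor(rate * n)` points removed uniformly;
#' * `"block"` — all points inside an axis-aligned sub-box holding
#'   approximately `block_frac` of the data removed (box centered at a
#'   seeded random in-domain point, half-widths scaled by bisection until
#'   the box captures the requested fraction), then `"random"` applied to
#'   the remainder.
#'
#' Fully reproducible: the same arguments and seed give the identical cloud.
#'
#' @param domain a [domain_spec()].
#' @param n number of points (random design).
#' @param design `"random"` (uniform rejection sampling) or `"grid"` (all
#'   in-domain voxel centers of resolution `grid` over the domain bounding
#'   box; `n` is ignored).
#' @param grid integer resolution `c(nx, ny, nz)` for the grid design.
#' @param signal signal name passed to [test_function()], or a function of
#'   an n x 3 matrix.
#' @param psnr peak signal-to-noise ratio in dB (mutually exclusive with
#'   `sigma`).
#' @param sigma noise SD: scalar, or function of an n x 3 matrix returning
#'   per-point SDs.
#' @param missing `"none"`, `"random"`, or `"block"`.
#' @param rate random-missing rate in `[0, 0.5]`.
#' @param block_frac fraction of data inside the missing block (default
#'   0.12).
#' @param seed integer seed.
#' @return list of class `point_cloud`: `x` (n x 3 locations), `w` (noisy
#'   responses), `m` (truth), `sigma` (per-point noise SD), `n`, plus the
#'   generating settings.
#' @export
simulate_point_cloud <- function(domain, n = 1000,
                                 design = c("random", "grid"), grid = NULL,
                                 signal = "m1", psnr = NULL, sigma = NULL,
                                 missing = c("none", "random", "block"),
                                 rate = 0, block_frac = 0.12, seed = 1) {
  design <- match.arg(design)
  missing <- match.arg(missing)
  if (!is.null(psnr) && !is.null(sigma))
    stop("'psnr' and 'sigma' are mutually exclusive")
  if (rate < 0 || rate > 0.5) stop("'rate' must be in [0, 0.5]")
  rs <- local_seed(seed)
  on.exit(restore_seed(rs))
  bbox <- domain_bbox(domain)

  if (design == "random") {
    x <- matrix(NA_real_, 0, 3)
    proposals <- 0L
    while (nrow(x) < n) {
      m_ <- max(2L * (n - nrow(x)), 1000L)
      proposals <- proposals + m_
      if (proposals > 1000 * n)
        stop("rejection sampling failed: domain too thin within its bounding box")
      cand <- cbind(stats::runif(m_, bbox[1, 1], bbox[2, 1]),
                    stats::runif(m_, bbox[1, 2], bbox[2, 2]),
                    stats::runif(m_, bbox[1, 3], bbox[2, 3]))
      x <- rbind(x, cand[domain_predicate(domain, cand), , drop = FALSE])
    }
    x <- x[seq_len(n), , drop = FALSE]
  } else {
    if (is.null(grid)) stop("grid design requires 'grid = c(nx, ny, nz)'")
    gx <- voxel_centers(bbox, grid)
    x <- gx[domain_predicate(domain, gx), , drop = FALSE]
  }

  f <- if (is.function(signal)) signal
       else function(p) test_function(signal, p, bbox)
  m <- f(x)
  sig <- if (is.null(sigma) && is.null(psnr)) rep(0, nrow(x))
         else if (!is.null(psnr)) rep(sigma_from_psnr(max(abs(m)), psnr), nrow(x))
         else if (is.function(sigma)) sigma(x)
         else rep(sigma, nrow(x))
  if (any(sig < 0) || any(!is.finite(sig)))
    stop("noise SD must be finite and non-negative on the whole domain")
  w <- m + sig * stats::rnorm(nrow(x))

  keep <- seq_len(nrow(x))
  if (missing == "block") {
    keep <- keep[-missing_block(x, block_frac)]
  }
  if (missing %in% c("random", "block") && rate > 0) {
    drop_n <- floor(rate * length(keep))
    if (drop_n > 0) keep <- keep[-sample(length(keep), drop_n)]
  }
  keep <- sort(keep)
  structure(list(x = x[keep, , drop = FALSE], w = w[keep], m = m[keep],
                 sigma = sig[keep], n = length(keep),
                 domain = domain, design = design, signal = signal,
                 missing = missing, rate = rate, seed = seed),
            class = "point_cloud")
}

voxel_centers <- function(bbox, grid) {
  grid <- as.integer(grid)
  cs <- (bbox[2, ] - bbox[1, ]) / grid
  as.matrix(expand.grid(
    x = bbox[1, 1] + (seq_len(grid[1]) - 0.5) * cs[1],
    y = bbox[1, 2] + (seq_len(grid[2]) - 0.5) * cs[2],
    z = bbox[1, 3] + (seq_len(grid[3]) - 0.5) * cs[3]))
}

# indices of points inside an axis-aligned box holding ~frac of the data:
# center at a random data point, half-widths = t * data half-ranges with t
# found by bisection on the captured fraction
missing_block <- function(x, frac) {
  n <- nrow(x)
  center <- x[sample(n, 1L), ]
  half <- (apply(x, 2, max) - apply(x, 2, min)) / 2
  inside_at <- function(t) {
    which(abs(x[, 1] - center[1]) <= t * half[1] &
          abs(x[, 2] - center[2]) <= t * half[2] &
          abs(x[, 3] - center[3]) <= t * half[3])
  }
  lo <- 0; hi <- 2
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (length(inside_at(mid)) / n < frac) lo <- mid else hi <- mid
  }
  inside_at(hi)
}

#' Heteroscedastic noise profile
#'
#' The distance-based noise profile used in the standard-error study:
#' `sigma(p) = c0 - ||p - anchor||`, decreasing away from the anchor point.
#' Positivity over the intended domain is checked at generation time by
#' [simulate_point_cloud()].
#'
#' @param c0 offset (default 6).
#' @param anchor length-3 anchor point (default `c(1.25, 0, 0)`).
#' @return a function of an n x 3 matrix returning per-point SDs.
#' @export
sigma_distance <- function(c0 = 6, anchor = c(1.25, 0, 0)) {
  force(c0); force(anchor)
  function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
    c0 - sqrt((p[, 1] - anchor[1])^2 + (p[, 2] - anchor[2])^2 +
                (p[, 3] - anchor[3])^2)
  }
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d points (%s design, %s domain)\n",
              x$n, x$design, x$domain$name))
  if (x$missing != "none")
    cat(sprintf("  missing scheme: %s (rate %.2f)\n", x$missing, x$rate))
  invisible(x)
}
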