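test_that("domain predicates follow their closed-form geometry", {
  box <- domain_spec("box_with_hole")
  expect_false(domain_predicate(box, c(1.5, 0.5, 0.5)))   # hole center
  expect_true(domain_predicate(box, c(1.5, 0.1, 0.5)))    # shell
  expect_true(domain_predicate(box, c(0.2, 0.5, 0.5)))
  expect_false(domain_predicate(box, c(-0.1, 0.5, 0.5)))  # outside outer box

  hs <- domain_spec("horseshoe3d")
  expect_false(domain_predicate(hs, c(0.75, 0, 0.25)))    # gap mid-angle
  expect_true(domain_predicate(hs, c(-0.75, 0, 0.25)))    # arc mid-radius
  expect_true(domain_predicate(hs, c(0.5, 0.75, 0.25)))   # arm
  expect_true(domain_predicate(hs, c(0.5, -0.75, 0.25)))  # mirrored arm
  expect_false(domain_predicate(hs, c(0.5, 0.75, 0.6)))   # above thickness
  expect_false(domain_predicate(hs, c(0, 0, 0.25)))       # inside inner radius
  # without arms the wedge is the gap
  hs0 <- domain_spec("horseshoe3d", arm_length = 0)
  ang <- 10 * pi / 180
  expect_false(domain_predicate(hs0, c(0.75 * cos(ang), 0.75 * sin(ang), 0.2)))
  ang2 <- 25 * pi / 180
  expect_true(domain_predicate(hs0, c(0.75 * cos(ang2), 0.75 * sin(ang2), 0.2)))

  expect_error(domain_spec("box_with_hole",
                           hole = rbind(c(-1, 0, 0), c(2, 1, 1))),
               "strictly inside")
  expect_error(domain_spec("horseshoe3d", gap_deg = 0), "gap")
})

test_that("test signals are finite, and the high-frequency variants rougher", {
  set.seed(71)
  p <- matrix(runif(3e5), ncol = 3)
  for (nm in c("m1", "m2", "m3", "m4")) {
    v <- test_function(nm, p)
    expect_true(all(is.finite(v)))
    expect_lt(max(abs(v)), 10)
  }
  expect_error(test_function("m9", p), "unknown")

  # empirical total variation over a fixed probe grid
  tv <- function(nm) {
    g <- seq(0.025, 0.975, length.out = 20)
    gr <- as.matrix(expand.grid(x = g, y = g, z = g))
    v <- array(test_function(nm, gr), c(20, 20, 20))
    sum(abs(diff(v))) + sum(abs(aperm(apply(v, c(1, 3), diff), c(2, 1, 3)))) +
      sum(abs(apply(v, c(1, 2), diff)))
  }
  expect_gt(tv("m2"), tv("m1"))
  expect_gt(tv("m4"), tv("m3"))
})

test_that("PSNR calibration round-trips and sets the empirical noise scale", {
  expect_equal(sigma_from_psnr(1, 20), 0.1)
  expect_equal(sigma_from_psnr(2, 5), 2 / 10^0.25, tolerance = 1e-12)
  sig <- sigma_from_psnr(3.7, 12.3)
  expect_equal(20 * log10(3.7 / sig), 12.3, tolerance = 1e-12)
  expect_error(sigma_from_psnr(1, Inf))

  dom <- domain_spec("unit_box")
  cl <- simulate_point_cloud(dom, n = 1e5, signal = "m1", psnr = 10,
                             seed = 72)
  sd_target <- sigma_from_psnr(max(abs(cl$m)), 10)
  expect_lt(abs(stats::sd(cl$w - cl$m) / sd_target - 1), 0.02)
})

test_that("generated clouds respect the domain, counts, and seeds", {
  dom <- domain_spec("box_with_hole")
  cl <- simulate_point_cloud(dom, n = 5000, signal = "m2", psnr = 5,
                             seed = 73)
  expect_equal(cl$n, 5000L)
  expect_true(all(domain_predicate(dom, cl$x)))
  cl_b <- simulate_point_cloud(dom, n = 5000, signal = "m2", psnr = 5,
                               seed = 73)
  expect_identical(cl$w, cl_b$w)
  expect_identical(cl$x, cl_b$x)

  clm <- simulate_point_cloud(dom, n = 10000, signal = "m1", psnr = 10,
                              missing = "random", rate = 0.3, seed = 74)
  expect_equal(clm$n, 7000L)

  hs <- domain_spec("horseshoe3d")
  clh <- simulate_point_cloud(hs, n = 2000, signal = "m3", psnr = 10,
                              seed = 75)
  expect_true(all(domain_predicate(hs, clh$x)))
})

test_that("grid design voxel counts match the declared geometry calibration", {
  dom <- domain_spec("box_with_hole")
  lo <- simulate_point_cloud(dom, design = "grid", grid = c(60, 20, 20),
                             signal = "m1", psnr = 10, seed = 76)
  hi <- simulate_point_cloud(dom, design = "grid", grid = c(75, 25, 25),
                             signal = "m1", psnr = 10, seed = 76)
  expect_lt(abs(lo$n / 22160 - 1), 0.1)
  expect_lt(abs(hi$n / 42600 - 1), 0.1)
})

test_that("block missing removes a contiguous sub-box of about the set fraction", {
  dom <- domain_spec("box_with_hole")
  full <- simulate_point_cloud(dom, n = 20000, signal = "m1", psnr = 10,
                               seed = 77)
  blk <- simulate_point_cloud(dom, n = 20000, signal = "m1", psnr = 10,
                              missing = "block", block_frac = 0.12, seed = 77)
  removed_frac <- 1 - blk$n / full$n
  expect_lt(abs(removed_frac - 0.12), 0.02)
  # removed points form an axis-aligned box: the kept cloud has a box-shaped
  # void exactly where the removed points were
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  removed <- full$x[!(key(full$x) %in% key(blk$x)), , drop = FALSE]
  expect_equal(nrow(removed), full$n - blk$n)
  lo <- apply(removed, 2, min); hi <- apply(removed, 2, max)
  inside_box <- blk$x[, 1] >= lo[1] & blk$x[, 1] <= hi[1] &
    blk$x[, 2] >= lo[2] & blk$x[, 2] <= hi[2] &
    blk$x[, 3] >= lo[3] & blk$x[, 3] <= hi[3]
  expect_equal(sum(inside_box), 0L)

  # block + random combines both reductions
  both <- simulate_point_cloud(dom, n = 20000, signal = "m1", psnr = 10,
                               missing = "block", block_frac = 0.12,
                               rate = 0.25, seed = 77)
  expect_equal(both$n, blk$n - floor(0.25 * blk$n))
})

test_that("heteroscedastic profile is positive and decreasing from the anchor", {
  hs <- domain_spec("horseshoe3d")
  sigf <- sigma_distance(c0 = 6, anchor = c(1.25, 0, 0))
  cl <- simulate_point_cloud(hs, n = 5000, signal = "m3", sigma = sigf,
                             seed = 78)
  expect_true(all(cl$sigma > 0))
  d_anchor <- sqrt(rowSums(sweep(cl$x, 2, c(1.25, 0, 0))^2))
  expect_equal(cl$sigma, 6 - d_anchor)
  # a negative profile on the domain is rejected
  expect_error(simulate_point_cloud(hs, n = 100, signal = "m3",
                                    sigma = sigma_distance(c0 = 0.1),
                                    seed = 79),
               "non-negative")
})
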