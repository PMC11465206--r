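test_that("multi-index table has the right size, order, and rank bijection", {
  expect_equal(nrow(multiindex_table(1)), 4L)
  expect_equal(nrow(multiindex_table(2)), 10L)
  expect_equal(nrow(multiindex_table(3)), 20L)
  expect_error(multiindex_table(-1))
  for (d in 1:5) {
    tbl <- multiindex_table(d)
    expect_true(all(rowSums(tbl) == d))
    # lexicographic, i outermost descending
    key <- tbl %*% ((d + 1)^(3:0))
    expect_true(all(diff(key) < 0))
    expect_equal(tpst3d:::multiindex_rank(tbl, d), seq_len(nrow(tbl)))
  }
})

test_that("Bernstein basis: values, partition of unity, 0^0 convention", {
  expect_equal(bernstein_eval(2, c(1, 1, 0, 0), c(0.5, 0.5, 0, 0)), 0.5)
  expect_equal(bernstein_eval(3, c(3, 0, 0, 0), c(1, 0, 0, 0)), 1)
  expect_equal(bernstein_eval(3, c(1, 1, 1, 0), rep(0.25, 4)), 0.09375)
  expect_error(bernstein_eval(2, c(1, 1, 1, 0), c(1, 0, 0, 0)), "summing")

  set.seed(21)
  b <- matrix(stats::rexp(1000 * 4), ncol = 4)
  b <- b / rowSums(b)
  b[1:10, 1] <- 0  # boundary values exercise 0^0 = 1
  b[1:10, ] <- b[1:10, ] / rowSums(b[1:10, ])
  for (d in 1:6) {
    tbl <- multiindex_table(d)
    tot <- rowSums(vapply(seq_len(nrow(tbl)), function(r) {
      bernstein_eval(d, tbl[r, ], b)
    }, numeric(nrow(b))))
    expect_lt(max(abs(tot - 1)), 1e-12)
  }
})

test_that("B-form evaluation: direct and de Casteljau agree; exact cases", {
  v <- unit_corner_tet
  # constant-one coefficients give the constant function
  expect_equal(bform_eval(rep(1, 20), v, rbind(c(2, -1, 3)), 3), 1)
  # d=1 with gamma = e2 is the coordinate x on the corner tet
  expect_equal(bform_eval(c(0, 1, 0, 0), v, c(0.3, 0.2, 0.1), 1), 0.3)

  set.seed(22)
  for (d in 2:4) {
    vt <- random_tet()
    g <- rnorm(choose(d + 3, 3))
    p <- matrix(runif(30, -0.5, 1), ncol = 3)
    expect_equal(bform_eval(g, vt, p, d),
                 bform_eval(g, vt, p, d, method = "decasteljau"),
                 tolerance = 1e-12)
  }
})

test_that("per-tet polynomial reproduction via lattice interpolation", {
  set.seed(23)
  for (d in 2:5) {
    vt <- random_tet()
    tbl <- multiindex_table(d)  # reuse as exponent table for random polys
    ex <- tbl[, 1:3]
    cf <- rnorm(nrow(ex))
    f <- function(p) {
      out <- numeric(nrow(p))
      for (r in seq_len(nrow(ex)))
        out <- out + cf[r] * p[, 1]^ex[r, 1] * p[, 2]^ex[r, 2] *
          p[, 3]^ex[r, 3]
      out
    }
    g <- bform_from_function(vt, d, f)
    b <- matrix(stats::rexp(100 * 4), ncol = 4); b <- b / rowSums(b)
    p <- b %*% vt
    err <- max(abs(bform_eval(g, vt, p, d) - f(p)))
    expect_lt(err / max(abs(f(p))), 1e-9)
  }
})

test_that("degree elevation preserves the represented polynomial", {
  set.seed(24)
  for (d in 1:4) {
    vt <- random_tet()
    g <- rnorm(choose(d + 3, 3))
    ge <- tpst3d:::degree_elevate(g, d)
    p <- matrix(runif(45, -0.2, 1), ncol = 3)
    expect_equal(bform_eval(ge, vt, p, d + 1L), bform_eval(g, vt, p, d),
                 tolerance = 1e-12)
  }
})

test_that("direction barycentrics are the affine increments and sum to zero", {
  v <- unit_corner_tet
  expect_equal(direction_barycentric(v, c(1, 0, 0)), c(-1, 1, 0, 0))
  set.seed(25)
  for (rep in 1:20) {
    vt <- random_tet()
    expect_equal(direction_barycentric(vt, vt[2, ] - vt[1, ]),
                 c(-1, 1, 0, 0), tolerance = 1e-10)
    u <- rnorm(3)
    a <- direction_barycentric(vt, u)
    expect_lt(abs(sum(a)), 1e-12)
    p <- runif(3)
    expect_equal(drop(barycentric_coords(vt, p + u) -
                        barycentric_coords(vt, p)), a, tolerance = 1e-9)
  }
})

test_that("directional derivative recurrence matches finite differences", {
  v <- unit_corner_tet
  gx <- bform_from_function(v, 3, function(p) p[, 1])
  a <- direction_barycentric(v, c(1, 0, 0))
  d1 <- directional_derivative_coeffs(gx, a, 3)
  expect_equal(bform_eval(d1, v, rbind(runif(3)), 2), 1, tolerance = 1e-12)
  # two derivatives of an affine function vanish
  gaff <- bform_from_function(v, 3, function(p) 1 + p[, 1] - 2 * p[, 3])
  d2 <- directional_derivative_coeffs(
    directional_derivative_coeffs(gaff, a, 3), a, 2)
  expect_lt(max(abs(d2)), 1e-12)

  set.seed(26)
  for (rep in 1:10) {
    vt <- random_tet()
    d <- sample(2:4, 1)
    g <- rnorm(choose(d + 3, 3))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    a <- direction_barycentric(vt, u)
    dg <- directional_derivative_coeffs(g, a, d)
    p <- matrix(runif(15, 0.1, 0.4), ncol = 3)
    h <- 1e-5
    fd <- (bform_eval(g, vt, p + h * rep(1, nrow(p)) %o% u, d) -
           bform_eval(g, vt, p - h * rep(1, nrow(p)) %o% u, d)) / (2 * h)
    an <- bform_eval(dg, vt, p, d - 1L)
    expect_lt(max(abs(fd - an)) / max(abs(an) + 1e-8), 1e-6)
  }
  expect_error(directional_derivative_coeffs(c(1), c(0, 0, 0, 0), 0))
})

test_that("Cartesian derivative operators are exact and commute", {
  v <- unit_corner_tet
  gx2 <- bform_from_function(v, 3, function(p) p[, 1]^2)
  G <- cartesian_derivative_operator(v, 3, c(2, 0, 0))
  expect_equal(as.numeric(G %*% gx2), rep(2, 4), tolerance = 1e-12)
  gxy <- bform_from_function(v, 3, function(p) p[, 1] * p[, 2])
  Gxy <- cartesian_derivative_operator(v, 3, c(1, 1, 0))
  expect_equal(as.numeric(Gxy %*% gxy), rep(1, 4), tolerance = 1e-12)
  gaff <- bform_from_function(v, 2, function(p) p[, 1] - p[, 2] + 2)
  for (al in list(c(2, 0, 0), c(1, 1, 0), c(0, 1, 1))) {
    Ga <- cartesian_derivative_operator(v, 2, al)
    expect_lt(max(abs(Ga %*% gaff)), 1e-12)
  }
  expect_error(cartesian_derivative_operator(v, 1, c(2, 0, 0)))

  set.seed(27)
  for (rep in 1:10) {
    vt <- random_tet()
    ax <- sort(sample(1:3, 2))  # mixed second derivative, both orders
    a1 <- integer(3); a1[ax[1]] <- 1L
    a2 <- integer(3); a2[ax[2]] <- 1L
    G12 <- cartesian_derivative_operator(vt, 3, a1 + a2)
    lo1 <- cartesian_derivative_operator(vt, 2, a2) %*%
      cartesian_derivative_operator(vt, 3, a1)
    lo2 <- cartesian_derivative_operator(vt, 2, a1) %*%
      cartesian_derivative_operator(vt, 3, a2)
    expect_lt(max(abs(G12 - lo1)), 1e-12 * max(1, max(abs(G12))))
    expect_lt(max(abs(lo1 - lo2)), 1e-12 * max(1, max(abs(G12))))
  }
})

test_that("design matrix rows live in one block, sum to one, flag outside", {
  single <- tet_mesh(unit_corner_tet, matrix(1:4, 1))
  sp1 <- spline_space(single, 3, 1)
  set.seed(28)
  b <- matrix(stats::rexp(20 * 4), ncol = 4); b <- b / rowSums(b)
  pin <- b %*% unit_corner_tet
  des <- design_matrix(sp1, rbind(pin, c(2, 2, 2)))
  expect_equal(dim(des$B), c(21L, 20L))
  expect_true(des$outside[21])
  expect_equal(Matrix::rowSums(des$B)[1:20], rep(1, 20), tolerance = 1e-12)
  expect_equal(Matrix::rowSums(des$B)[21], 0)

  mesh <- two_tet_mesh()
  sp <- spline_space(mesh, 2, 0)
  p <- matrix(runif(60), ncol = 3)
  des2 <- design_matrix(sp, p)
  loc <- des2$tet
  for (i in which(!is.na(loc))) {
    blk <- (loc[i] - 1) * 10 + 1:10
    expect_equal(sum(des2$B[i, -blk] != 0), 0)
  }
})
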