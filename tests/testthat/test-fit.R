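make_cloud <- function(n, f, sd = 0, seed = 51, lim = c(0, 1)) {
  set.seed(seed)
  p <- cbind(runif(n, lim[1], lim[2]), runif(n, 0, 1), runif(n, 0, 1))
  list(x = p, w = f(p) + if (sd > 0) rnorm(n, sd = sd) else 0)
}

test_that("noiseless affine data are recovered exactly at any rho", {
  mesh <- structured_mesh(c(2, 2, 2), rbind(c(0, 0, 0), c(1, 1, 1)))
  f <- function(p) 1 + 2 * p[, 1] - p[, 2] + 0.5 * p[, 3]
  cl <- make_cloud(4000, f)
  q <- make_cloud(500, f, seed = 52)$x
  for (rho in c(0, 1, 1e4)) {
    fit <- tpst(cl$x, cl$w, mesh, d = 3, r = 1, rho = rho)
    expect_lt(max(abs(predict(fit, q) - f(q))), 1e-8)
  }
})

test_that("noiseless degree-d polynomials are reproduced at rho = 0", {
  mesh <- structured_mesh(c(2, 2, 2), rbind(c(0, 0, 0), c(1, 1, 1)))
  set.seed(53)
  for (rep in 1:3) {
    cf <- rnorm(4)
    f <- function(p) cf[1] * p[, 1]^3 + cf[2] * p[, 1] * p[, 2] * p[, 3] +
      cf[3] * p[, 3]^2 + cf[4]
    cl <- make_cloud(4000, f, seed = 53 + rep)
    fit <- tpst(cl$x, cl$w, mesh, d = 3, r = 1, rho = 0)
    q <- make_cloud(400, f, seed = 99 + rep)$x
    expect_lt(max(abs(predict(fit, q) - f(q))), 1e-6)
  }
})

test_that("QR-reduced solution equals the dense KKT oracle", {
  meshes <- list(two_tet_mesh(),
                 structured_mesh(c(2, 1, 1), rbind(c(0, 0, 0), c(2, 1, 1))))
  set.seed(54)
  draws <- 0
  for (mesh in meshes) {
    for (conf in list(c(2, 0), c(3, 1))) {
      sp <- spline_space(mesh, conf[1], conf[2])
      xmax <- max(mesh$vertices[, 1])
      for (rep in 1:3) {
        draws <- draws + 1
        n <- 400
        p <- cbind(runif(n, 0, xmax), runif(n), runif(n))
        keep <- !is.na(locate_points(mesh, p))
        p <- p[keep, , drop = FALSE]
        w <- rnorm(nrow(p))
        rho <- stats::rexp(1)
        fit <- tpst(p, w, mesh, d = conf[1], r = conf[2], rho = rho,
                    null_method = "svd")
        gam_kkt <- kkt_oracle(sp, p, w, rho)
        expect_lt(max(abs(fit$gamma - gam_kkt)) / max(abs(gam_kkt)), 1e-8)
      }
    }
  }
  expect_gte(draws, 12)
})

test_that("shrinkage: RSS grows, energy falls, rho -> Inf hits the affine fit", {
  mesh <- structured_mesh(c(2, 2, 2), rbind(c(0, 0, 0), c(1, 1, 1)))
  f <- function(p) sin(pi * p[, 1]) * cos(pi * p[, 2]) + p[, 3]
  cl <- make_cloud(3000, f, sd = 0.3)
  sc <- 1
  fits <- lapply(10^seq(-4, 6, by = 1), function(rho) {
    tpst(cl$x, cl$w, mesh, d = 3, r = 1, rho = rho * sc)
  })
  rss <- vapply(fits, function(f_) f_$rss, numeric(1))
  en <- vapply(fits, function(f_) f_$energy, numeric(1))
  edf <- vapply(fits, function(f_) f_$edf, numeric(1))
  expect_true(all(diff(rss) >= -1e-10 * max(rss)))
  expect_true(all(diff(en) <= 1e-10 * max(en)))
  expect_true(all(diff(edf) <= 1e-8 * max(edf)))

  fit_inf <- tpst(cl$x, cl$w, mesh, d = 3, r = 1, rho = 1e10)
  fit_0 <- tpst(cl$x, cl$w, mesh, d = 3, r = 1, rho = 0)
  expect_lt(fit_inf$energy, 1e-6 * fit_0$energy)
  aff <- stats::lm.fit(cbind(1, cl$x), cl$w)
  expect_lt(max(abs(fit_inf$fitted - aff$fitted.values)) /
              max(abs(aff$fitted.values)), 1e-3)
  expect_equal(fit_inf$edf, 4, tolerance = 1e-4)
})

test_that("rho -> Inf limit for r = 0 is the continuous piecewise-linear fit", {
  mesh <- structured_mesh(c(2, 1, 1), rbind(c(0, 0, 0), c(2, 1, 1)))
  f <- function(p) sin(2 * p[, 1]) + p[, 2] * p[, 3]
  cl <- make_cloud(3000, f, sd = 0.2, lim = c(0, 2))
  fit_inf <- tpst(cl$x, cl$w, mesh, d = 2, r = 0, rho = 1e10)
  fit_pl <- tpst(cl$x, cl$w, mesh, d = 1, r = 0, rho = 0)
  expect_lt(max(abs(fit_inf$fitted - fit_pl$fitted)) /
              max(abs(fit_pl$fitted)), 1e-3)
})

test_that("effective df: projector trace at rho = 0, monotone decrease", {
  mesh <- two_tet_mesh()
  cl <- make_cloud(500, function(p) p[, 1] + p[, 2])
  keep <- !is.na(locate_points(mesh, cl$x))
  fit <- tpst(cl$x[keep, ], cl$w[keep], mesh, d = 1, r = 0, rho = 0)
  expect_equal(fit$q, 5L)
  expect_equal(fit$edf, 5, tolerance = 1e-8)

  fit2 <- tpst(cl$x[keep, ], cl$w[keep], mesh, d = 3, r = 1, rho = 1)
  expect_lte(effective_df(fit2, rho = 10), fit2$edf + 1e-8)
  expect_gte(effective_df(fit2, rho = 0.1), fit2$edf - 1e-8)
})

test_that("GCV: single-point grid is returned; smooth truth favors penalty", {
  mesh <- structured_mesh(c(2, 2, 2), rbind(c(0, 0, 0), c(1, 1, 1)))
  cl <- make_cloud(1500, function(p) p[, 1], sd = 0.5)
  fit1 <- tpst(cl$x, cl$w, mesh, d = 2, r = 0, rho_grid = 0.37)
  expect_equal(fit1$rho, 0.37)
  expect_equal(nrow(fit1$selection$table), 1L)

  # affine truth + noise: the heavy-penalty GCV should win almost always
  base <- tpst(cl$x, cl$w, mesh, d = 2, r = 0, rho = 1)
  scale_ <- sum(diag(base$system$Gr)) / sum(diag(base$system$Pr))
  wins <- 0
  for (s in 1:50) {
    set.seed(100 + s)
    wnew <- 2 + cl$x[, 1] - cl$x[, 2] + rnorm(nrow(cl$x), sd = 0.5)
    f2 <- tpst(cl$x, wnew, mesh, d = 2, r = 0,
               rho_grid = c(1e-8 * scale_, 1e6 * scale_))
    tab <- f2$selection$table
    if (tab$gcv[2] < tab$gcv[1]) wins <- wins + 1
    expect_true(all(diff(tab$rss) >= -1e-10 * max(tab$rss)))
  }
  expect_gte(wins, 40)
})

test_that("block CV partitions tets, never trains on held-out points", {
  mesh <- structured_mesh(c(2, 2, 2), rbind(c(0, 0, 0), c(1, 1, 1)))
  folds <- blockcv_folds(504, 5, seed = 3)
  expect_equal(length(folds), 504L)
  expect_equal(sort(unique(folds)), 1:5)
  expect_true(all(tabulate(folds, 5) > 0))
  expect_identical(folds, blockcv_folds(504, 5, seed = 3))

  cl <- make_cloud(2500, function(p) sin(pi * p[, 1]) + p[, 2], sd = 0.3)
  fit <- tpst(cl$x, cl$w, mesh, d = 2, r = 0, select = "blockcv",
              folds = 4, seed = 11)
  sel <- fit$selection
  expect_equal(sel$method, "blockcv")
  expect_equal(length(sel$folds), nrow(mesh$tets))
  expect_true(fit$rho %in% sel$table$rho)
  expect_equal(sel$table$rho[which.min(sel$table$cv)], fit$rho)
})

test_that("under-determined and out-of-domain inputs are handled explicitly", {
  mesh <- two_tet_mesh()
  set.seed(55)
  p <- matrix(runif(30, 0.05, 0.2), ncol = 3)  # few points, inside tet 1
  expect_error(tpst(p, rnorm(10), mesh, d = 3, r = 1, rho = 0),
               "under-determined")
  # outside points dropped with a warning
  cl <- make_cloud(600, function(p) p[, 1])
  p2 <- rbind(cl$x, c(9, 9, 9))
  expect_warning(fit <- tpst(p2, c(cl$w, 0), mesh, d = 2, r = 0, rho = 0.1),
                 "outside")
  expect_equal(fit$n_used, sum(!is.na(locate_points(mesh, cl$x))))
  # strict mode errors on a singular system (data-free tets at rho = 0)
  mesh4 <- structured_mesh(c(4, 1, 1), rbind(c(0, 0, 0), c(4, 1, 1)))
  clA <- make_cloud(800, function(p) p[, 1])  # only covers x in [0, 1]
  expect_error(tpst(clA$x, clA$w, mesh4, d = 1, r = 0, rho = 0, ridge = 0),
               "singular")
  fitr <- tpst(clA$x, clA$w, mesh4, d = 1, r = 0, rho = 0)
  expect_gt(fitr$ridge_used, 0)
})

test_that("constraint residual of the fitted coefficients is negligible", {
  mesh <- kuhn_cube_mesh()
  cl <- make_cloud(1200, function(p) sin(p[, 1] + p[, 2]), sd = 0.1)
  for (conf in list(c(3, 1), c(2, 0))) {
    fit <- tpst(cl$x, cl$w, mesh, d = conf[1], r = conf[2], rho = 0.01)
    H <- smoothness_constraints(fit$space)$H
    expect_lt(max(abs(H %*% fit$gamma)), 1e-9 * max(1, max(abs(fit$gamma))))
  }
})

test_that("predictions agree across incident tets and reproduce fitted values", {
  mesh <- kuhn_cube_mesh()
  cl <- make_cloud(1500, function(p) p[, 1]^2 + p[, 2], sd = 0.05)
  fit <- tpst(cl$x, cl$w, mesh, d = 2, r = 0, rho = 0.01)
  # vertices are shared by many tets: evaluation must not depend on which
  vpred <- predict(fit, mesh$vertices)
  M <- fit$space$M
  for (vi in seq_len(nrow(mesh$vertices))) {
    inc <- which(apply(mesh$tets == vi, 1, any))
    vals <- vapply(inc, function(t) {
      bform_eval(fit$gamma[(t - 1) * M + 1:M],
                 mesh$vertices[mesh$tets[t, ], ], mesh$vertices[vi, ],
                 fit$space$d)
    }, numeric(1))
    expect_lt(max(abs(vals - vpred[vi])), 1e-9)
  }
  expect_true(is.na(predict(fit, c(10, 0, 0))))
  expect_equal(predict(fit, fit$x), fit$fitted, tolerance = 1e-12)
})

test_that("formula interface and methods behave like the default one", {
  mesh <- kuhn_cube_mesh()
  cl <- make_cloud(800, function(p) p[, 1] + sin(p[, 2]), sd = 0.1)
  df <- data.frame(x = cl$x[, 1], y = cl$x[, 2], z = cl$x[, 3], w = cl$w)
  f1 <- tpst(w ~ x + y + z, data = df, mesh = mesh, d = 2, r = 0, rho = 0.05)
  f2 <- tpst(cl$x, cl$w, mesh, d = 2, r = 0, rho = 0.05)
  expect_equal(f1$theta, f2$theta)
  expect_equal(coef(f1), coef(f2))
  expect_equal(length(attr(coef(f1), "theta")), f1$q)
  expect_equal(residuals(f1), cl$w - fitted(f1))
  expect_output(print(f1), "TPST fit")
  expect_output(print(summary(f1)), "compression")
  sims <- simulate(f1, nsim = 3, seed = 8)
  expect_equal(dim(sims), c(f1$n_used, 3L))
  expect_identical(sims, simulate(f1, nsim = 3, seed = 8))
})

test_that("refitting with new responses matches a from-scratch fit", {
  mesh <- kuhn_cube_mesh()
  cl <- make_cloud(900, function(p) p[, 1], sd = 0.2)
  fit <- tpst(cl$x, cl$w, mesh, d = 2, r = 0, rho = 0.3)
  set.seed(56)
  wnew <- cl$x[, 2] + rnorm(fit$n_used, sd = 0.2)
  f_refit <- tpst_refit(fit, wnew)
  f_scratch <- tpst(fit$x, wnew, mesh, d = 2, r = 0, rho = 0.3)
  expect_equal(f_refit$theta, f_scratch$theta, tolerance = 1e-12)
  expect_equal(f_refit$rss, f_scratch$rss, tolerance = 1e-10)
})
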