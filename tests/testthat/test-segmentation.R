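test_that("half-overlapping window grids follow the counting formula", {
  g <- segment_series(rnorm(1000), 200, 0.5)
  expect_equal(g$starts, seq(0L, 800L, by = 100L))
  expect_equal(g$n_windows, 9L)
  g1 <- segment_series(rnorm(200), 200)
  expect_equal(g1$starts, 0L)
  expect_equal(g1$n_windows, 1L)
  expect_error(segment_series(rnorm(199), 200), "shorter than one window")
  # trailing samples are dropped
  g2 <- segment_series(rnorm(1050), 200, 0.5)
  expect_equal(max(g2$starts) + g2$window_len, 1000L)
})

test_that("design matrix enumerates all monomials up to the order", {
  expect_equal(ncol(design_matrix(rnorm(50), 2, 2)$X), 6L)
  expect_equal(ncol(design_matrix(rnorm(50), 1, 3)$X), 4L)
  expect_equal(ncol(design_matrix(rnorm(50), 3, 2)$X), 10L)
  # m=2, p=2 columns are {1, x_t, x_{t-1}, x_t^2, x_t x_{t-1}, x_{t-1}^2}
  x <- c(2, 3, 5, 7)
  d <- design_matrix(x, 2, 2)
  expect_equal(d$y, c(5, 7))
  expect_equal(d$X[1, ], c(1, 3, 2, 9, 6, 4))     # lags (x_t=3, x_{t-1}=2)
  expect_equal(d$X[2, ], c(1, 5, 3, 25, 15, 9))
})

test_that("noise-free map coefficients are recovered exactly", {
  # affine map x_{t+1} = 0.5 + 0.3 x_t
  x <- numeric(60); x[1] <- 0.9
  for (t in 2:60) x[t] <- 0.5 + 0.3 * x[t - 1]
  fit <- fit_poly_map(x[1:20], 1, 1, ridge = 0)
  expect_equal(fit$coefs, c(0.5, 0.3), tolerance = 1e-8)
  # closed-form least-squares oracle on the same design
  d <- design_matrix(x[1:20], 1, 1)
  expect_equal(fit$coefs, drop(solve(crossprod(d$X), crossprod(d$X, d$y))),
               tolerance = 1e-8)
  expect_false(fit$degenerate)
  # logistic map, m=1, p=2 -> (0, 3.9, -3.9)
  y <- numeric(200); y[1] <- 0.31
  for (t in 2:200) y[t] <- 3.9 * y[t - 1] * (1 - y[t - 1])
  fit2 <- fit_poly_map(y, 1, 2)
  expect_equal(fit2$coefs, c(0, 3.9, -3.9), tolerance = 1e-6)
  expect_lt(fit2$residual_var, 1e-12)
})

test_that("degenerate and undersized segments are handled", {
  fit <- fit_poly_map(rep(2.5, 40), 1, 2)
  expect_true(fit$degenerate)
  expect_equal(fit$residual_var, 0)
  expect_equal(fit$coefs, c(2.5, 0, 0))
  expect_error(fit_poly_map(rnorm(15), 3, 2), "cannot identify")
})

test_that("coefficient distance matches a brute-force oracle", {
  expect_equal(coef_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(coef_distance(c(1, 2, 2), c(1, 0, 2)), 2)
  expect_error(coef_distance(1:3, 1:4), "differ in length")
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    brute <- 0
    for (j in 1:6) brute <- brute + (a[j] - b[j])^2
    expect_equal(coef_distance(a, b), sqrt(brute), tolerance = 1e-12)
  }
})

test_that("distance matrices are symmetric, zero-diagonal, right-shaped", {
  set.seed(2)
  x <- rnorm(600)
  grid <- segment_series(x, 100)
  models <- fit_segment_models(x, grid, m = 2, p = 1)
  D <- distance_matrix(models)
  expect_equal(dim(D), c(grid$n_windows, grid$n_windows))
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, nrow(D)))
  expect_true(all(D >= 0))
})

test_that("identical windows give an all-zero distance matrix", {
  seg <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 100))
  x <- rep(seg, 3)
  grid <- segment_series(x, 100, 0)   # non-overlapping identical windows
  models <- fit_segment_models(x, grid, m = 2, p = 1)
  expect_equal(max(distance_matrix(models)), 0, tolerance = 1e-10)
})

test_that("between-regime distances exceed within-regime distances", {
  sim <- two_regime_signal(31, noise_frac = 0)
  grid <- segment_series(sim$x, 128)
  models <- fit_segment_models(sim$x, grid)
  D <- distance_matrix(models)
  wt <- window_truth(sim$truth$labels, grid)
  pure <- vapply(grid$starts, function(s0)
    length(unique(sim$truth$labels[(s0 + 1):(s0 + 128)])) == 1L, logical(1))
  w1 <- which(pure & wt == 1); w2 <- which(pure & wt == 2)
  within <- c(D[w1, w1][upper.tri(D[w1, w1])],
              D[w2, w2][upper.tri(D[w2, w2])])
  between <- as.vector(D[w1, w2])
  expect_gt(median(between), max(median(within) * 2, 0))
  expect_gt(mean(outer(within, between, `<`)), 0.9)
})

test_that("residual variance is non-increasing in polynomial order", {
  set.seed(4)
  for (i in 1:5) {
    seg <- as.numeric(arima.sim(list(ar = 0.6), 80)) + rnorm(80, 0, 0.2)
    rv <- vapply(0:3, function(p) fit_poly_map(seg, 1, p)$residual_var,
                 numeric(1))
    expect_true(all(diff(rv) <= 1e-12))
  }
})

test_that("map parameters are recovered from generator output", {
  # the Henon map as a 2-lag quadratic: x_{t+1} = 1 - 1.4 x_t^2 + 0.3 x_{t-1}
  # in monomial order {1, x_t, x_{t-1}, x_t^2, x_t x_{t-1}, x_{t-1}^2}
  coefs <- c(1, 0, 0.3, -1.4, 0, 0)
  reg <- regime_spec(1, "polynomial_map", m = 2, p = 2, coefs = coefs,
                     init_range = c(-0.1, 0.1))
  sim <- make_regime_signal(list(reg), dwell_s = 2, length_s = 2, fs = 128,
                            seed = 5)
  fit <- fit_poly_map(sim$signal, 2, 2)
  expect_equal(fit$coefs, coefs, tolerance = 1e-6)
})

test_that("optional per-window normalisation removes amplitude information", {
  y <- numeric(256); y[1] <- 0.37
  for (t in 2:256) y[t] <- 3.9 * y[t - 1] * (1 - y[t - 1])
  x <- c(y, 3 * y)                  # same dynamics at 3x the amplitude
  grid <- segment_series(x, 128, 0)
  raw <- fit_segment_models(x, grid, m = 1, p = 2)
  nrm <- fit_segment_models(x, grid, m = 1, p = 2, normalize = TRUE)
  # raw fits see different quadratic coefficients across the amplitude step;
  # z-scored windows are literally identical and fit identically
  expect_gt(coef_distance(raw$coefs[1, ], raw$coefs[3, ]), 0.5)
  expect_lt(coef_distance(nrm$coefs[1, ], nrm$coefs[3, ]), 1e-8)
  expect_true(isTRUE(nrm$normalize))
})
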