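# A small hand-built design: n subjects, each measured in every group x
# condition cell, with a per-cell mean matrix mu (cells ordered group
# slowest, condition fastest) plus noise.
toy_pls <- function(n_subj, groups, conditions, mu, noise_sd = 0.1,
                    seed = 1) {
  set.seed(seed)
  cells <- expand.grid(condition = conditions, group = groups,
                       stringsAsFactors = FALSE)[, c("group", "condition")]
  meta <- NULL
  X <- NULL
  for (s in seq_len(n_subj)) {
    for (ci in seq_len(nrow(cells))) {
      X <- rbind(X, mu[ci, ] + rnorm(ncol(mu), 0, noise_sd))
      meta <- rbind(meta, data.frame(subject = sprintf("s%02d", s),
                                     group = cells$group[ci],
                                     condition = cells$condition[ci]))
    }
  }
  meta$group <- factor(meta$group, levels = groups)
  meta$condition <- factor(meta$condition, levels = conditions)
  list(X = X, meta = meta)
}

test_that("cell means match a brute-force average", {
  d <- toy_pls(4, c("g1", "g2"), c("a", "b"),
               matrix(rnorm(12), 4, 3), noise_sd = 0.5, seed = 2)
  cm <- build_cell_means(d$X, d$meta)
  expect_equal(dim(cm$M), c(4L, 3L))
  for (i in seq_len(4)) {
    rows <- d$meta$group == cm$cells$group[i] &
      d$meta$condition == cm$cells$condition[i]
    for (j in 1:3) expect_equal(cm$M[i, j], mean(d$X[rows, j]))
  }
  # one participant per cell: means equal raw rows
  d1 <- toy_pls(1, c("g1", "g2"), c("a", "b"), matrix(0, 4, 3),
                noise_sd = 1, seed = 3)
  cm1 <- build_cell_means(d1$X, d1$meta)
  expect_equal(unname(cm1$M), unname(d1$X))
  # duplicating every participant leaves cell means unchanged
  cm2 <- build_cell_means(rbind(d$X, d$X), rbind(d$meta, d$meta))
  expect_equal(cm2$M, cm$M)
})

test_that("empty cells are reported by name", {
  d <- toy_pls(2, c("g1", "g2"), c("a", "b"), matrix(0, 4, 2))
  drop_rows <- !(d$meta$group == "g2" & d$meta$condition == "b")
  expect_error(build_cell_means(d$X[drop_rows, ], d$meta[drop_rows, ]),
               "empty cell")
})

test_that("mean-centered PLS recovers a single-electrode contrast", {
  # 2 cells x 3 electrodes differing only on electrode 1
  mu <- rbind(c(1, 0.5, -0.2), c(3, 0.5, -0.2))
  d <- toy_pls(5, c("g1", "g2"), "only", mu, noise_sd = 0)
  fit <- mean_centered_pls(d$X, d$meta)
  expect_equal(sum(fit$d > 1e-10), 1L)
  expect_equal(abs(fit$electrode_loadings[, 1]), c(1, 0, 0))
  expect_equal(fit$condition_loadings[1, 1], -fit$condition_loadings[2, 1])
  # identical cell means: everything zero
  d0 <- toy_pls(3, c("g1", "g2"), c("a", "b"), matrix(1, 4, 3),
                noise_sd = 0)
  expect_equal(mean_centered_pls(d0$X, d0$meta)$d, rep(0, 3),
               tolerance = 1e-12)
})

test_that("singular values conserve the energy of the decomposed matrix", {
  for (seed in 1:5) {
    d <- toy_pls(3, c("g1", "g2", "g3"), c("a", "b"),
                 matrix(rnorm(30), 6, 5), noise_sd = 0.3, seed = seed)
    fit <- mean_centered_pls(d$X, d$meta)
    expect_equal(sum(fit$d^2), sum(fit$decomposed^2), tolerance = 1e-10)
    dsn <- linear_trend_contrast(c("g1", "g2", "g3"), c("a", "b"))
    cfit <- contrast_pls(d$X, d$meta, dsn)
    expect_equal(sum(cfit$d^2), sum(cfit$decomposed^2), tolerance = 1e-10)
  }
})

test_that("contrast PLS projects onto a priori directions", {
  groups <- c("g1", "g2", "g3")
  # cell means increase linearly over groups on electrode 2 only
  mu <- cbind(rep(0, 6), rep(c(-1, 0, 1), each = 2), rep(0, 6))
  d <- toy_pls(4, groups, c("a", "b"), mu, noise_sd = 0)
  dsn <- linear_trend_contrast(groups, c("a", "b"))
  fit <- contrast_pls(d$X, d$meta, dsn)
  expect_equal(sum(fit$d > 1e-10), 1L)
  expect_equal(abs(fit$electrode_loadings[, 1]), c(0, 1, 0))
  # a contrast orthogonal to the true differences sees nothing
  dsn0 <- condition_contrast(groups, c("a", "b"))
  expect_equal(contrast_pls(d$X, d$meta, dsn0)$d, rep(0, 1),
               tolerance = 1e-10)
  # electrode permutation equivariance
  perm <- c(3, 1, 2)
  fitp <- contrast_pls(d$X[, perm], d$meta, dsn)
  expect_equal(fitp$d, fit$d)
  expect_equal(abs(fitp$electrode_loadings[, 1]),
               abs(fit$electrode_loadings[perm, 1]))
  # malformed contrasts are rejected
  expect_error(contrast_pls(d$X, d$meta, matrix(1, 6, 1)), "sum to zero")
  bad <- cbind(dsn, dsn * 2)
  expect_error(contrast_pls(d$X, d$meta, bad), "orthogonal")
})

test_that("permutation p-values are extreme for huge effects, seeded", {
  mu <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10), c(20, 20), c(20, 20))
  d <- toy_pls(4, c("g1", "g2", "g3"), c("a", "b"), mu, noise_sd = 0.05)
  pt <- permutation_test(d$X, d$meta, "mean_centered", n_perm = 100,
                         seed = 5)
  expect_equal(pt$perm_p[1], 0)
  pt2 <- permutation_test(d$X, d$meta, "mean_centered", n_perm = 100,
                          seed = 5)
  expect_identical(pt$perm_p, pt2$perm_p)
  expect_error(permutation_test(d$X, d$meta, n_perm = 50), "n_perm")
})

test_that("tiny designs warn that distinct permutations are exhausted", {
  mu <- rbind(c(0, 0), c(1, 1))
  d <- toy_pls(2, "g1", c("a", "b"), mu, noise_sd = 0.1)
  expect_warning(permutation_test(d$X, d$meta, "mean_centered",
                                  n_perm = 100, seed = 1),
                 "fewer distinct")
})

test_that("null permutation p-values are approximately uniform", {
  # measure-level null cohorts; KS check over repeated simulations
  pvals <- vapply(1:120, function(i) {
    tab <- null_measures_table(n_subjects = 8, n_channels = 4,
                               seed = 7000 + i)
    pd <- pls_data(tab, "n_states")
    permutation_test(pd$X, pd$meta, "mean_centered", n_perm = 100,
                     seed = i)$perm_p[1]
  }, numeric(1))
  # plain exceedance proportions live on {0, 1/n_perm, ...}; jitter within
  # a bin before the continuous KS test
  ks <- suppressWarnings(ks.test(pvals + runif(120, 0, 0.01), "punif"))
  expect_gt(ks$p.value, 0.01)
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.15)
})

test_that("bootstrap ratios flag stable electrodes and zero-variance ones", {
  groups <- c("g1", "g2", "g3")
  mu <- cbind(rep(c(-2, 0, 2), each = 2), rep(0, 6), rep(0, 6))
  d <- toy_pls(6, groups, c("a", "b"), mu, noise_sd = 0.3, seed = 9)
  dsn <- linear_trend_contrast(groups, c("a", "b"))
  bs <- bootstrap_ratios(d$X, d$meta, "contrast", dsn, n_boot = 200,
                         seed = 2)
  expect_gte(abs(bs$bsr[1, 1]), 2)
  bs2 <- bootstrap_ratios(d$X, d$meta, "contrast", dsn, n_boot = 200,
                          seed = 2)
  expect_identical(bs$bsr, bs2$bsr)
  expect_error(bootstrap_ratios(d$X[1:12, ], d$meta[1:12, ], "contrast",
                                dsn, n_boot = 100),
               "at least 3 participants")
})

test_that("degenerate bootstrap distributions return the Inf sentinel", {
  # noise-free data: every resample gives identical loadings
  mu <- rbind(c(1, 0), c(1, 0), c(2, 0), c(2, 0))
  d <- toy_pls(4, c("g1", "g2"), c("a", "b"), mu, noise_sd = 0)
  bs <- bootstrap_ratios(d$X, d$meta, "mean_centered", n_boot = 100,
                         seed = 3)
  expect_true(any(bs$zero_se))
  expect_true(all(is.infinite(bs$bsr[bs$zero_se])))
})
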