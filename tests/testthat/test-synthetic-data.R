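test_that("a single regime yields one run covering every sample", {
  reg <- regime_spec(1, "ar2_oscillator", freq_hz = 10, damping = 0.9)
  sim <- make_regime_signal(list(reg), dwell_s = 2, length_s = 4, fs = 128,
                            seed = 3)
  expect_equal(nrow(sim$truth$runs), 1L)
  expect_equal(sim$truth$runs$length, 4 * 128)
  expect_equal(length(sim$signal), 4 * 128)
  expect_equal(sim$truth$n_regimes, 1L)
})

test_that("fixed dwell alternation produces the forced run structure", {
  regs <- list(regime_spec(1, "ar2_oscillator", freq_hz = 6, damping = 0.95),
               regime_spec(2, "ar2_oscillator", freq_hz = 11, damping = 0.9))
  sim <- make_regime_signal(regs, dwell_s = 2, length_s = 10, fs = 128,
                            seed = 1)
  expect_equal(nrow(sim$truth$runs), 5L)
  expect_equal(sim$truth$runs$regime, c(1L, 2L, 1L, 2L, 1L))
  expect_equal(sim$truth$runs$length, rep(256L, 5))
  expect_equal(sim$truth$switch_times, seq(0L, 1024L, by = 256L))
})

test_that("a noise-free logistic-map regime follows its recurrence exactly", {
  reg <- regime_spec(1, "polynomial_map", m = 1, p = 2,
                     coefs = c(0, 3.9, -3.9), init_range = c(0.2, 0.8))
  sim <- make_regime_signal(list(reg), dwell_s = 4, length_s = 4, fs = 100,
                            seed = 9)
  x <- sim$signal
  # direct recurrence oracle within the single run
  expect_equal(x[-1], 3.9 * x[-length(x)] * (1 - x[-length(x)]),
               tolerance = 1e-12)
  expect_true(all(x >= 0 & x <= 1))
})

test_that("divergent maps and sub-3-sample dwells are rejected", {
  bad <- regime_spec(7, "polynomial_map", m = 1, p = 2,
                     coefs = c(0, 5.2, 0), init_range = c(1.5, 2))
  expect_error(make_regime_signal(list(bad), dwell_s = 1, length_s = 1,
                                  fs = 100, seed = 1),
               "diverged in regime 7")
  ok <- regime_spec(1, "ar2_oscillator", freq_hz = 5, damping = 0.9)
  expect_error(make_regime_signal(list(ok), dwell_s = 0.01, length_s = 1,
                                  fs = 100, seed = 1),
               "shorter than 3 samples")
})

test_that("generation is reproducible and seeds change signals, not truth", {
  regs <- default_regime_library(2)
  a <- make_regime_signal(regs, 1.5, 6, 128, seed = 5)
  b <- make_regime_signal(regs, 1.5, 6, 128, seed = 5)
  c <- make_regime_signal(regs, 1.5, 6, 128, seed = 6)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$signal, c$signal)))
  expect_identical(a$truth$runs, c$truth$runs)
})

test_that("run lengths always partition the epoch", {
  for (seed in 1:10) {
    set.seed(seed)
    K <- sample(1:4, 1)
    dm <- sample(c("fixed", "exponential"), 1)
    sim <- make_regime_signal(default_regime_library(K),
                              dwell_s = runif(1, 0.5, 2), length_s = 6,
                              fs = 128, seed = seed + 100, dwell_model = dm)
    expect_equal(sum(sim$truth$runs$length), length(sim$signal))
    expect_equal(length(sim$truth$labels), length(sim$signal))
    # labels agree with runs
    expect_equal(rep(sim$truth$runs$regime, sim$truth$runs$length),
                 sim$truth$labels)
  }
})

test_that("oscillator regimes peak at their centre frequency", {
  fs <- 256
  for (f0 in c(6, 11, 27)) {
    reg <- regime_spec(1, "ar2_oscillator", freq_hz = f0, damping = 0.95)
    # average the periodogram over realisations: the peak location check
    # concerns the generating spectrum, not one realisation's jitter
    acc <- NULL
    for (seed in 1:5) {
      sim <- make_regime_signal(list(reg), dwell_s = 60, length_s = 60,
                                fs = fs, seed = seed * 17)
      psd <- dynstates:::welch_psd(sim$signal, fs, window_s = 4)
      acc <- if (is.null(acc)) psd$power else acc + psd$power
    }
    peak <- psd$freq[which.max(acc)]
    expect_lte(abs(peak - f0), 0.25 + 1e-9)  # within one bin at 4 s windows
  }
})

test_that("cohort counting, effect direction and seed contract hold", {
  spec <- cohort_spec(n_subjects = 6, groups = c("g1", "g2", "g3"),
                      conditions = c("eo", "ec"), n_channels = 2,
                      epoch_length_s = 2, fs = 64,
                      n_epochs_per_condition = 2,
                      regimes_by_group = c(1, 1, 1), base_regimes = 1,
                      dwell_by_group = c(2, 1.5, 1), noise_frac = 0.05,
                      seed = 2)
  coh <- make_cohort(spec)
  # 6 subjects x 3 visits rows; 2 conditions x 2 epochs each
  expect_equal(nrow(unique(coh$manifest[, c("subject", "group")])), 18L)
  expect_equal(length(coh$epochs), 6 * 3 * 2 * 2)
  # per-group epoch count: 6 subjects x 2 conditions x 2 epochs
  expect_equal(sum(coh$manifest$group == "g1"), 24L)
  # dwell decreasing with group by construction (single regime: dwell is
  # capped by epoch length, compare realised switch counts instead)
  dw <- aggregate(true_dwell_s ~ group, coh$truth, mean)
  expect_true(all(diff(dw$true_dwell_s[match(c("g1", "g2", "g3"),
                                             dw$group)]) <= 0))
  coh2 <- make_cohort(spec)
  expect_identical(coh$epochs[[1]]$data, coh2$epochs[[1]]$data)
  spec3 <- spec; spec3$seed <- 99L
  coh3 <- make_cohort(spec3)
  expect_false(isTRUE(all.equal(coh$epochs[[1]]$data,
                                coh3$epochs[[1]]$data)))
  expect_equal(coh$truth$true_K, coh3$truth$true_K)
})

test_that("focal channels carry the localized regime-count effect", {
  spec <- cohort_spec(n_subjects = 2, groups = c("g1", "g2"),
                      group_ages = c(10, 11.5),
                      conditions = "eo", n_channels = 4,
                      focal_channels = 1:2, epoch_length_s = 4, fs = 128,
                      regimes_by_group = c(2, 4), base_regimes = 2,
                      dwell_by_group = c(1, 1), seed = 4)
  coh <- make_cohort(spec)
  tr <- coh$truth
  expect_true(all(tr$true_K[tr$channel <= 2 & tr$group == "g2"] == 4))
  expect_true(all(tr$true_K[tr$channel > 2] == 2))
  expect_true(all(tr$true_K[tr$group == "g1"] == 2))
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_subjects = 4, groups = c("a", "b"),
                           regimes_by_group = c(2, 2, 2)),
               "one\\s+entry per group")
  expect_error(cohort_spec(n_subjects = 4, n_channels = 4,
                           focal_channels = 9),
               "subset of 1..n_channels")
})

test_that("an optional mixing matrix spreads sources across channels", {
  mix <- matrix(c(1, 0.5, 0.5, 1), 2)
  spec <- cohort_spec(n_subjects = 1, groups = "g1", group_ages = 10,
                      conditions = "eo", n_channels = 2,
                      epoch_length_s = 2, fs = 64,
                      regimes_by_group = 1, dwell_by_group = 2,
                      noise_frac = 0, mixing = mix, seed = 6)
  spec0 <- spec; spec0$mixing <- NULL
  mixed <- make_cohort(spec)$epochs[[1]]$data
  pure <- make_cohort(spec0)$epochs[[1]]$data
  expect_equal(unname(mixed), unname(mix %*% pure), tolerance = 1e-12)
  expect_error(cohort_spec(n_subjects = 1, n_channels = 3,
                           mixing = diag(2)),
               "n_channels x n_channels")
})
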