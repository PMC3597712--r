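# Independent oracles and fixture builders shared across the test files.
# Every oracle is a direct, brute-force computation with no code in common
# with the implementation it checks.

# Exhaustive exemplar-subset search for the affinity-propagation objective:
# for every nonempty subset E of points taken as exemplars, net similarity
# is sum of preferences over E plus, for each other point, its best
# similarity to a member of E. Feasible for N <= 8 (255 subsets).
ap_exhaustive <- function(s, preference) {
  n <- nrow(s)
  preference <- rep_len(preference, n)
  best <- -Inf
  best_E <- NULL
  for (mask in seq_len(2^n - 1)) {
    E <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    val <- sum(preference[E])
    for (i in setdiff(seq_len(n), E)) val <- val + max(s[i, E])
    if (val > best) {
      best <- val
      best_E <- E
    }
  }
  list(value = best, exemplars = best_E)
}

# Plain loop run-length encoder, independent of base rle().
rle_oracle <- function(labels) {
  runs <- list()
  start <- 1L
  for (i in seq_along(labels)) {
    if (i == length(labels) || labels[i + 1L] != labels[i]) {
      runs[[length(runs) + 1L]] <- c(value = labels[start],
                                     first = start, last = i)
      start <- i + 1L
    }
  }
  do.call(rbind, runs)
}

# Two well-separated point clouds in the plane; blob SD 1, centre distance
# sep_ratio times the typical within-blob spread.
blob_instance <- function(n1, n2, sep_ratio, seed) {
  set.seed(seed)
  shift <- sep_ratio * 4   # within-blob diameter is ~4 SD
  pts <- rbind(matrix(stats::rnorm(n1 * 2), ncol = 2),
               matrix(stats::rnorm(n2 * 2, mean = shift), ncol = 2))
  list(D = as.matrix(dist(pts)), truth = rep(1:2, c(n1, n2)))
}

# The two-oscillator scenario: 6 Hz narrowband vs 11 Hz broadband regimes,
# fixed dwell, observation noise as a fraction of the signal SD.
two_regime_signal <- function(seed, dwell_s = 2, length_s = 30, fs = 256,
                              noise_frac = 0.1) {
  regs <- default_regime_library(2)
  sim <- make_regime_signal(regs, dwell_s = dwell_s, length_s = length_s,
                            fs = fs, seed = seed)
  set.seed(seed + 10000L)
  x <- sim$signal + stats::rnorm(length(sim$signal),
                                 0, noise_frac * stats::sd(sim$signal))
  list(x = x - mean(x), truth = sim$truth, fs = fs)
}

# Majority ground-truth regime per window of a grid.
window_truth <- function(sample_labels, grid) {
  vapply(grid$starts, function(s0) {
    tb <- table(sample_labels[(s0 + 1):(s0 + grid$window_len)])
    as.integer(names(tb)[which.max(tb)])
  }, integer(1))
}

# Agreement between two label vectors after best matching, for two states.
two_state_agreement <- function(est, truth) {
  max(mean((est == est[1]) == (truth == truth[1])),
      mean((est != est[1]) == (truth == truth[1])))
}

# Best-permutation label agreement for small numbers of states.
best_perm_agreement <- function(est, truth) {
  eu <- unique(est)
  tu <- unique(truth)
  if (length(eu) > 6) stop("too many states for exhaustive matching")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  k <- max(length(eu), length(tu))
  tu_pad <- c(tu, rep(NA, k - length(tu)))
  best <- 0
  for (p in perms(tu_pad)) {
    mapped <- p[match(est, eu)]
    hit <- !is.na(mapped) & mapped == truth
    best <- max(best, mean(hit))
  }
  best
}
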