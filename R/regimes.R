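#' Specify one quasi-stationary regime
#'
#' A regime is a stationary generating process that a simulated channel dwells
#' in before switching. Two families are supported: a damped stochastic
#' oscillator (an AR(2) process parameterised by its resonance frequency and
#' pole radius), and a deterministic polynomial map iterated from a random
#' initial value, e.g. the logistic map.
#'
#' @param regime_id Integer label carried into the ground truth.
#' @param dynamics `"ar2_oscillator"` or `"polynomial_map"`.
#' @param freq_hz Oscillator centre frequency in Hz (ar2 only). Must lie
#'   strictly between 0 and the Nyquist frequency of the sampling rate the
#'   regime is later simulated at.
#' @param damping Pole radius in (0, 1) (ar2 only); values near 1 give a
#'   narrowband rhythm, smaller values a broadband one.
#' @param innov_sd Innovation standard deviation of the oscillator, signal
#'   units (ar2 only). Scales the regime's amplitude.
#' @param m,p Embedding dimension and polynomial order of a map regime.
#' @param coefs Coefficient vector of a map regime, one entry per monomial of
#'   degree `<= p` in the `m` lagged values, in the order returned by
#'   [monomial_exponents()]. The logistic map `x <- r*x*(1-x)` is
#'   `m = 1, p = 2, coefs = c(0, r, -r)`.
#' @param init_range Interval the initial value of a map regime is drawn from
#'   uniformly at each entry into the regime.
#' @param noise_sd Additive Gaussian observation noise applied to this
#'   regime's samples, signal units.
#' @return An object of class `regime_spec`.
#' @examples
#' regime_spec(1, "ar2_oscillator", freq_hz = 10, damping = 0.95)
#' regime_spec(2, "polynomial_map", m = 1, p = 2, coefs = c(0, 3.9, -3.9),
#'             init_range = c(0.2, 0.8))
#' @export
regime_spec <- function(regime_id, dynamics = c("ar2_oscillator", "polynomial_map"),
                        freq_hz = NULL, damping = 0.95, innov_sd = 1,
                        m = NULL, p = NULL, coefs = NULL,
                        init_range = c(0.2, 0.8), noise_sd = 0) {
  dynamics <- match.arg(dynamics)
  if (dynamics == "ar2_oscillator") {
    stopifnot(is.numeric(freq_hz), length(freq_hz) == 1L, freq_hz > 0,
              damping > 0, damping < 1, innov_sd > 0)
  } else {
    stopifnot(is.numeric(coefs), !is.null(m), !is.null(p),
              length(coefs) == nrow(monomial_exponents(m, p)))
  }
  structure(list(regime_id = as.integer(regime_id), dynamics = dynamics,
                 freq_hz = freq_hz, damping = damping, innov_sd = innov_sd,
                 m = m, p = p, coefs = coefs, init_range = init_range,
                 noise_sd = noise_sd),
            class = "regime_spec")
}

#' Monomial exponent table
#'
#' Enumerates all monomials of total degree `<= p` in `m` variables, ordered
#' by total degree and, within a degree, by descending exponent of the first
#' (most recent) lag. This fixed order defines the meaning of every
#' coefficient vector in the package: for `m = 2, p = 2` the columns are
#' `1, x_t, x_{t-1}, x_t^2, x_t*x_{t-1}, x_{t-1}^2`.
#'
#' @param m Number of lagged values.
#' @param p Maximal total degree.
#' @return Integer matrix with `choose(m + p, p)` rows and `m` columns; row i
#'   gives the exponents of monomial i.
#' @export
monomial_exponents <- function(m, p) {
  stopifnot(m >= 1, p >= 0)
  compositions <- function(total, parts) {
    if (parts == 1L) return(matrix(total, 1L, 1L))
    out <- NULL
    for (first in seq(total, 0L)) {
      rest <- compositions(total - first, parts - 1L)
      out <- rbind(out, cbind(first, rest))
    }
    out
  }
  ex <- NULL
  for (d in 0:p) ex <- rbind(ex, compositions(d, m))
  dimnames(ex) <- NULL
  storage.mode(ex) <- "integer"
  ex
}

ar2_coefficients <- function(freq_hz, damping, fs) {
  # place the spectral peak (not the pole angle) at freq_hz:
  # the AR(2) spectrum peaks where cos(w) = cos(theta) * (1 + r^2) / (2 r)
  r <- damping
  ct <- cos(2 * pi * freq_hz / fs) * 2 * r / (1 + r^2)
  c(2 * r * ct, -r^2)
}

# Iterate one regime for n samples, continuing from `state` (most recent last).
# Returns clean (pre-observation-noise) samples.
simulate_regime_run <- function(regime, n, fs, state) {
  if (regime$dynamics == "ar2_oscillator") {
    if (regime$freq_hz >= fs / 2)
      stop("regime ", regime$regime_id, ": centre frequency ", regime$freq_hz,
           " Hz is not below the Nyquist frequency ", fs / 2, " Hz")
    b <- ar2_coefficients(regime$freq_hz, regime$damping, fs)
    prev <- c(0, 0)
    if (length(state) >= 2) prev <- utils::tail(state, 2)
    x <- numeric(n)
    e <- stats::rnorm(n, 0, regime$innov_sd)
    for (t in seq_len(n)) {
      x[t] <- b[1] * prev[2] + b[2] * prev[1] + e[t]
      prev <- c(prev[2], x[t])
    }
  } else {
    m <- regime$m
    ex <- monomial_exponents(m, regime$p)
    x0 <- stats::runif(m, regime$init_range[1], regime$init_range[2])
    prev <- x0            # oldest first
    x <- numeric(n)
    for (t in seq_len(n)) {
      lags <- rev(prev)   # x_t, x_{t-1}, ...
      mono <- apply(ex, 1L, function(e) prod(lags^e))
      x[t] <- sum(regime$coefs * mono)
      if (!is.finite(x[t]) || abs(x[t]) > 1e6)
        stop("polynomial map trajectory diverged in regime ",
             regime$regime_id)
      prev <- c(prev, x[t])
      prev <- prev[(length(prev) - m + 1L):length(prev)]
    }
  }
  x
}

#' Simulate a piecewise-stationary single-channel signal
#'
#' Alternates through the supplied regimes (cyclically), dwelling in each for
#' a fixed or exponentially distributed time, and records the exact
#' sample-wise ground truth. Oscillator regimes continue from the last two
#' samples at a switch so the signal has no jumps; map regimes restart from
#' their `init_range`.
#'
#' @param regimes List of [regime_spec()] objects (at least one).
#' @param dwell_s Mean dwell time per regime visit, seconds.
#' @param length_s Total signal length, seconds (`>= dwell_s`).
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; identical inputs give identical output.
#' @param dwell_model `"fixed"` (every visit lasts exactly `dwell_s`) or
#'   `"exponential"` (visit lengths drawn from an exponential with mean
#'   `dwell_s`, truncated below at 3 samples).
#' @return A list with `signal` (numeric vector of `length_s * fs` samples)
#'   and `truth`, itself a list with per-sample regime `labels`, a `runs`
#'   data frame (regime, start, length; starts are 0-based samples),
#'   `switch_times` (0-based start sample of every run), the number of
#'   distinct regimes visited `n_regimes`, and `mean_dwell_samples`.
#' @export
make_regime_signal <- function(regimes, dwell_s, length_s, fs, seed = 1L,
                               dwell_model = c("fixed", "exponential")) {
  dwell_model <- match.arg(dwell_model)
  if (inherits(regimes, "regime_spec")) regimes <- list(regimes)
  stopifnot(length(regimes) >= 1, dwell_s > 0, length_s >= dwell_s)
  n_total <- round(length_s * fs)
  n_dwell <- round(dwell_s * fs)
  if (n_dwell < 3L) stop("dwell time is shorter than 3 samples")
  set.seed(as.integer(seed))
  x <- numeric(0)
  labels <- integer(0)
  run_regime <- integer(0)
  run_len <- integer(0)
  k <- 0L
  while (length(x) < n_total) {
    k <- k + 1L
    reg <- regimes[[(k - 1L) %% length(regimes) + 1L]]
    len <- if (dwell_model == "fixed") n_dwell else
      max(3L, stats::rgeom(1L, 1 / n_dwell) + 1L)
    len <- min(len, n_total - length(x))
    if (len <= 0L) break
    seg <- simulate_regime_run(reg, len, fs, state = x)
    if (reg$noise_sd > 0) seg <- seg + stats::rnorm(len, 0, reg$noise_sd)
    x <- c(x, seg)
    labels <- c(labels, rep(reg$regime_id, len))
    run_regime <- c(run_regime, reg$regime_id)
    run_len <- c(run_len, len)
  }
  # merge consecutive visits to the same regime (possible when K = 1 or a
  # visit is truncated at the epoch end) into single runs
  merged <- rle(run_regime)
  run_regime <- merged$values
  run_len <- as.integer(tapply(run_len,
                               rep(seq_along(merged$lengths),
                                   merged$lengths), sum))
  runs <- data.frame(regime = run_regime, length = run_len,
                     start = cumsum(c(0L, run_len[-length(run_len)])))
  truth <- list(labels = labels,
                runs = runs[, c("regime", "start", "length")],
                switch_times = runs$start,
                n_regimes = length(unique(run_regime)),
                mean_dwell_samples = mean(run_len))
  list(signal = x, truth = truth)
}

#' Default regime library
#'
#' Returns `K` oscillator regimes whose windowed map coefficients separate
#' cleanly: regimes alternate between narrowband (pole radius near 1) and
#' broadband dynamics at well-spaced centre frequencies, mirroring the
#' narrowband alpha vs broadband beta character of real EEG rhythms.
#'
#' @param K Number of regimes (1 to 5).
#' @param innov_sd Innovation scale shared by all regimes.
#' @return List of `K` [regime_spec()] objects.
#' @export
default_regime_library <- function(K, innov_sd = 1) {
  stopifnot(K >= 1, K <= 5)
  freqs <- c(6, 11, 27, 30, 2.5)
  damps <- c(0.97, 0.75, 0.97, 0.72, 0.85)
  lapply(seq_len(K), function(k)
    regime_spec(k, "ar2_oscillator", freq_hz = freqs[k], damping = damps[k],
                innov_sd = innov_sd))
}
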