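hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# Averaged modified periodogram (Welch) of one channel: Hann-tapered
# segments, 50% overlap. Returns power at positive FFT bins.
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  nper <- round(window_s * fs)
  if (length(x) < nper)
    stop("signal shorter than one spectral window (", nper, " samples)")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- hann(nper)
  norm <- sum(w^2)
  acc <- numeric(nper %/% 2)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    f <- stats::fft(seg)
    p <- Mod(f[2:(nper %/% 2 + 1L)])^2 / norm
    acc <- acc + p
  }
  list(freq = (seq_len(nper %/% 2)) * fs / nper, power = acc / length(starts))
}

#' Relative spectral power of an epoch
#'
#' Power per frequency bin from an averaged modified periodogram
#' (Hann-tapered segments, 50% overlap), normalised per channel so the bins
#' inside the analysis band sum to 1. Relative power is therefore invariant
#' to overall amplitude scaling.
#'
#' @param epoch An [epoch_record()].
#' @param band Analysis band `c(low, high)` in Hz, inside `(0, fs/2)`.
#' @param window_s Spectral window length, seconds.
#' @return Data frame, one row per channel and frequency bin: subject,
#'   group, condition, epoch_index, channel, `freq` (Hz), `rel_power`.
#' @export
relative_power <- function(epoch, band = c(1, 30), window_s = 2) {
  stopifnot(inherits(epoch, "epoch_record"))
  if (band[1] <= 0 || band[2] >= epoch$fs / 2 || band[1] >= band[2])
    stop("band must lie strictly inside (0, Nyquist)")
  out <- NULL
  for (ch in seq_len(nrow(epoch$data))) {
    psd <- welch_psd(epoch$data[ch, ], epoch$fs, window_s)
    keep <- psd$freq >= band[1] & psd$freq <= band[2]
    rel <- psd$power[keep] / sum(psd$power[keep])
    out <- rbind(out, data.frame(
      subject = epoch$subject, group = epoch$group,
      condition = epoch$condition, epoch_index = epoch$epoch_index,
      channel = epoch$channel_names[ch], freq = psd$freq[keep],
      rel_power = rel))
  }
  out
}

#' Average relative power across epochs
#'
#' @param power Stacked [relative_power()] rows from several epochs.
#' @return One row per subject, group, condition, channel and frequency bin.
#' @export
average_power_over_epochs <- function(power) {
  stats::aggregate(rel_power ~ subject + group + condition + channel + freq,
                   data = power, FUN = mean)
}

#' First-order partial correlation
#'
#' Pearson correlation between `x` and `y` after controlling for `z`:
#' `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`.
#'
#' @param x,y,z Numeric vectors of equal length (>= 4).
#' @return Scalar in `[-1, 1]`.
#' @export
partial_correlation <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(x) == length(z), length(x) >= 4)
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("control variable is collinear with x or y")
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Partial correlation map between a non-stationarity measure and power
#'
#' For every channel and frequency bin, correlates one measure with relative
#' power across pooled subject-by-condition observations (groups and
#' conditions merged), controlling the other measure.
#'
#' @param measures Epoch-averaged measures table from [cohort_measures()].
#' @param power Relative-power table: `relative_power()` rows, averaged over
#'   epochs if several (any data frame with subject, group, condition,
#'   channel, freq, rel_power).
#' @param which Measure to correlate: `"n_states"` or `"mean_seg_len_s"`;
#'   the other one is the control.
#' @return Data frame: channel, freq, `r` (partial correlation; `NA` where
#'   fewer than 4 matched observations), `n`.
#' @export
power_nonstat_correlation <- function(measures, power,
                                      which = c("n_states",
                                                "mean_seg_len_s")) {
  which <- match.arg(which)
  other <- setdiff(c("n_states", "mean_seg_len_s"), which)
  merged <- merge(power,
                  measures[, c("subject", "group", "condition", "channel",
                               "n_states", "mean_seg_len_s")],
                  by = c("subject", "group", "condition", "channel"))
  if (nrow(merged) == 0L) stop("no matched rows between measures and power")
  out <- NULL
  for (ch in unique(merged$channel)) {
    sub <- merged[merged$channel == ch, ]
    for (f in unique(sub$freq)) {
      cell <- sub[sub$freq == f, ]
      r <- if (nrow(cell) >= 4L)
        partial_correlation(cell[[which]], cell$rel_power, cell[[other]])
      else NA_real_
      out <- rbind(out, data.frame(channel = ch, freq = f, r = r,
                                   n = nrow(cell)))
    }
  }
  out
}
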