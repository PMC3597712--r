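#' Specify a synthetic longitudinal cohort
#'
#' Describes a cohort in which every subject is seen once per group (groups
#' are longitudinal visits, as in a developmental design), in every condition,
#' for a fixed number of epochs. Each channel of each epoch is a
#' piecewise-stationary signal; the number of distinct regimes and their mean
#' dwell time are set per group, which is how age effects with known ground
#' truth are built in:
#'
#' * a *localized* effect: `regimes_by_group` sets the regime count K on the
#'   `focal_channels` only; all other channels use `base_regimes` regimes in
#'   every group;
#' * a *global* effect: `dwell_by_group` sets the mean dwell time (seconds)
#'   on every channel.
#'
#' @param n_subjects Number of subjects (each appears in every group).
#' @param groups Character vector of group/visit labels, in age order.
#' @param group_ages Mean age (years) per group; defaults to `10, 11.5, 13,
#'   ...` spaced 1.5 y apart.
#' @param age_sd Between-subject age jitter (years); a subject keeps the same
#'   jitter at every visit.
#' @param conditions Character vector of condition labels.
#' @param n_channels,focal_channels Channel count and the indices carrying
#'   the localized regime-count effect (may be empty).
#' @param epoch_length_s,fs Epoch length (seconds) and sampling rate (Hz).
#' @param n_epochs_per_condition Epochs per subject, group and condition.
#' @param regimes_by_group Integer vector (one per group): number of distinct
#'   regimes K on focal channels.
#' @param base_regimes K on non-focal channels (all groups).
#' @param dwell_by_group Numeric vector (one per group): mean dwell, seconds.
#' @param dwell_jitter_sd Lognormal sigma of a per-subject dwell multiplier
#'   (0 = every subject in a group shares the group dwell).
#' @param dwell_model `"fixed"` or `"exponential"` visit lengths.
#' @param noise_frac Observation noise SD as a fraction of each channel's
#'   clean signal SD.
#' @param couple_switch_to_slow If `TRUE`, a 2.5 Hz narrowband component is
#'   added to every channel with amplitude proportional to the channel's
#'   switch rate (inverse dwell), coupling faster state alternation to more
#'   low-frequency power.
#' @param focal_amplitude_states If `TRUE`, each focal channel carries an
#'   additional stationary 10 Hz component whose amplitude grows with that
#'   channel's regime count, so subjects visiting more states also carry
#'   more alpha power on focal channels.
#' @param focal_k_jitter If `TRUE`, each subject's focal-channel regime
#'   count is offset by -1, 0 or +1 (clamped to [2, 4]), giving
#'   between-subject state-count variation that is independent of the
#'   dwell-time structure.
#' @param mixing Optional channel-by-channel linear mixing matrix applied
#'   to every epoch (rows = observed channels), emulating volume-conduction
#'   spread of sources across electrodes; `NULL` (default) leaves channels
#'   independent.
#' @param seed Integer seed for the whole cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, groups = c("g1", "g2", "g3"),
                        group_ages = NULL, age_sd = 0.4,
                        conditions = c("eyes_open", "eyes_closed"),
                        n_channels = 8, focal_channels = integer(0),
                        epoch_length_s = 20, fs = 256,
                        n_epochs_per_condition = 1,
                        regimes_by_group = rep(2L, length(groups)),
                        base_regimes = regimes_by_group[1],
                        dwell_by_group = rep(2, length(groups)),
                        dwell_jitter_sd = 0,
                        dwell_model = c("fixed", "exponential"),
                        noise_frac = 0.1,
                        couple_switch_to_slow = FALSE,
                        focal_amplitude_states = FALSE,
                        focal_k_jitter = FALSE,
                        mixing = NULL,
                        seed = 1L) {
  dwell_model <- match.arg(dwell_model)
  if (is.null(group_ages)) group_ages <- 10 + 1.5 * (seq_along(groups) - 1)
  if (length(regimes_by_group) != length(groups) ||
      length(dwell_by_group) != length(groups) ||
      length(group_ages) != length(groups))
    stop("regimes_by_group, dwell_by_group and group_ages must have one ",
         "entry per group")
  stopifnot(n_subjects >= 1, n_channels >= 1,
            all(regimes_by_group >= 1), all(dwell_by_group > 0))
  if (length(focal_channels) &&
      !all(focal_channels %in% seq_len(n_channels)))
    stop("focal_channels must be a subset of 1..n_channels")
  if (!is.null(mixing) &&
      (!is.matrix(mixing) || any(dim(mixing) != n_channels)))
    stop("mixing must be an n_channels x n_channels matrix")
  structure(list(n_subjects = n_subjects, groups = groups,
                 group_ages = group_ages, age_sd = age_sd,
                 conditions = conditions, n_channels = n_channels,
                 focal_channels = focal_channels,
                 epoch_length_s = epoch_length_s, fs = fs,
                 n_epochs_per_condition = n_epochs_per_condition,
                 regimes_by_group = as.integer(regimes_by_group),
                 base_regimes = as.integer(base_regimes),
                 dwell_by_group = dwell_by_group,
                 dwell_jitter_sd = dwell_jitter_sd,
                 dwell_model = dwell_model, noise_frac = noise_frac,
                 couple_switch_to_slow = couple_switch_to_slow,
                 focal_amplitude_states = focal_amplitude_states,
                 focal_k_jitter = focal_k_jitter, mixing = mixing,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Null cohort at the measures level
#'
#' Generates an epoch-averaged measures table with no group or condition
#' effect: each subject's measures are a subject-level random effect plus
#' independent noise, identically distributed across all group-by-condition
#' cells. Used to study the calibration of the PLS permutation test, where
#' only the exchangeability of cell labels within subjects matters; the
#' scales default to what the signal pipeline typically produces.
#'
#' @param n_subjects,groups,conditions,n_channels Cohort shape.
#' @param base_n_states,base_seg_len Grand means of the two measures.
#' @param subject_sd,channel_sd,noise_sd Subject random effect, channel
#'   random effect, and residual SDs (applied to both measures on their own
#'   scales).
#' @param seed Integer seed.
#' @return Data frame in the format of `cohort_measures()$averaged`.
#' @export
null_measures_table <- function(n_subjects = 12, groups = c("g1", "g2", "g3"),
                                conditions = c("eyes_open", "eyes_closed"),
                                n_channels = 8, base_n_states = 2.5,
                                base_seg_len = 1.5, subject_sd = 0.3,
                                channel_sd = 0.1, noise_sd = 0.4,
                                seed = 1L) {
  set.seed(as.integer(seed))
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  channels <- paste0("ch", seq_len(n_channels))
  re_s <- matrix(stats::rnorm(n_subjects * 2, 0, subject_sd), n_subjects)
  re_c <- matrix(stats::rnorm(n_channels * 2, 0, channel_sd), n_channels)
  grid <- expand.grid(channel = channels, condition = conditions,
                      group = groups, subject = subjects,
                      stringsAsFactors = FALSE)
  si <- match(grid$subject, subjects)
  ci <- match(grid$channel, channels)
  n <- nrow(grid)
  grid$age <- NA_real_
  grid$n_states <- pmax(1, base_n_states + re_s[si, 1] + re_c[ci, 1] +
                          stats::rnorm(n, 0, noise_sd))
  grid$mean_seg_len_s <- pmax(0.1, base_seg_len + re_s[si, 2] +
                                re_c[ci, 2] + stats::rnorm(n, 0, noise_sd))
  grid$n_epochs <- 1L
  grid[, c("subject", "group", "age", "condition", "channel", "n_states",
           "mean_seg_len_s", "n_epochs")]
}

#' One epoch of one subject and condition
#'
#' @param data Channel-by-sample numeric matrix.
#' @param fs Sampling rate, Hz.
#' @param subject,group,condition,epoch_index Metadata labels.
#' @param age Subject age at this visit, years (optional).
#' @param channel_names Channel labels; default `ch1, ch2, ...`.
#' @param demean Subtract each channel's epoch mean (the package's only
#'   preprocessing assumption; inputs are otherwise taken as preprocessed).
#' @return Object of class `epoch_record`.
#' @export
epoch_record <- function(data, fs, subject, group, condition,
                         epoch_index = 1L, age = NA_real_,
                         channel_names = NULL, demean = TRUE) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), all(is.finite(data)), fs > 0)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(channel_names) == nrow(data))
  if (demean) data <- data - rowMeans(data)
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, subject = as.character(subject),
                 group = as.character(group), condition = as.character(condition),
                 epoch_index = as.integer(epoch_index), age = age,
                 channel_names = channel_names),
            class = "epoch_record")
}

#' @export
print.epoch_record <- function(x, ...) {
  cat(sprintf("<epoch_record> %s / %s / %s / epoch %d: %d channels x %d samples @ %g Hz\n",
              x$subject, x$group, x$condition, x$epoch_index,
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

# Regimes used by one channel of one subject/group cell.
channel_regimes <- function(spec, group_idx, channel, k_offset = 0L) {
  focal <- channel %in% spec$focal_channels
  K <- if (focal) spec$regimes_by_group[group_idx] else spec$base_regimes
  if (focal && k_offset != 0L) K <- min(4L, max(2L, K + k_offset))
  if (focal && spec$focal_amplitude_states) {
    # an alpha-burst ladder: a desynchronized broadband background state
    # plus up to three 10 Hz states of increasing amplitude and sharpening
    # resonance, so subjects with more states carry more alpha power and
    # the states remain dynamically separable
    damps <- c(0.75, 0.90, 0.97)
    innovs <- c(0.6, 1.6, 4.5)
    lapply(seq_len(K), function(k) {
      if (k == 1L)
        regime_spec(1L, "ar2_oscillator", freq_hz = 16, damping = 0.60,
                    innov_sd = 0.6)
      else
        regime_spec(k, "ar2_oscillator", freq_hz = 10,
                    damping = damps[k - 1L], innov_sd = innovs[k - 1L])
    })
  } else {
    default_regime_library(K)
  }
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates every epoch of a [cohort_spec()], channel by channel, with
#' deterministic per-epoch seeds derived from the cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `epochs` (list of [epoch_record()]), `manifest` (one
#'   row per epoch: subject, group, age, condition, epoch_index) and `truth`
#'   (one row per epoch and channel: true regime count `true_K`, realised
#'   mean dwell `true_dwell_s`, switch count).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  min_dwell <- min(spec$dwell_by_group)
  set.seed(spec$seed)
  subjects <- sprintf("s%02d", seq_len(spec$n_subjects))
  age_jitter <- stats::rnorm(spec$n_subjects, 0, spec$age_sd)
  dwell_mult <- if (spec$dwell_jitter_sd > 0)
    exp(stats::rnorm(spec$n_subjects, 0, spec$dwell_jitter_sd)) else
    rep(1, spec$n_subjects)
  k_off <- if (isTRUE(spec$focal_k_jitter))
    sample(c(-1L, 0L, 1L), spec$n_subjects, replace = TRUE) else
    integer(spec$n_subjects)
  epochs <- list()
  manifest <- NULL
  truth <- NULL
  eseed <- spec$seed
  for (si in seq_len(spec$n_subjects)) {
    for (gi in seq_along(spec$groups)) {
      age <- spec$group_ages[gi] + age_jitter[si]
      dwell <- spec$dwell_by_group[gi] * dwell_mult[si]
      for (cond in spec$conditions) {
        for (ep in seq_len(spec$n_epochs_per_condition)) {
          eseed <- eseed + 1L
          dat <- matrix(0, spec$n_channels, round(spec$epoch_length_s * spec$fs))
          for (ch in seq_len(spec$n_channels)) {
            regs <- channel_regimes(spec, gi, ch, k_off[si])
            sim <- make_regime_signal(regs, dwell_s = dwell,
                                      length_s = spec$epoch_length_s,
                                      fs = spec$fs,
                                      seed = eseed * 131L + ch,
                                      dwell_model = spec$dwell_model)
            x <- sim$signal
            if (spec$focal_amplitude_states &&
                ch %in% spec$focal_channels && length(regs) > 1L) {
              # the alpha-amplitude coupling: channels visiting more states
              # also carry a proportionally stronger 10 Hz component
              x <- x + simulate_regime_run(
                regime_spec(98L, "ar2_oscillator", freq_hz = 10,
                            damping = 0.95,
                            innov_sd = 0.3 * (length(regs) - 1L)),
                length(x), spec$fs, state = numeric(0))
            }
            if (spec$couple_switch_to_slow) {
              # faster state alternation comes with more low-frequency power
              x <- x + simulate_regime_run(
                regime_spec(99L, "ar2_oscillator", freq_hz = 2.5,
                            damping = 0.97,
                            innov_sd = 0.1 * min_dwell / dwell),
                length(x), spec$fs, state = numeric(0))
            }
            if (spec$noise_frac > 0)
              x <- x + stats::rnorm(length(x), 0,
                                    spec$noise_frac * stats::sd(x))
            dat[ch, ] <- x
            truth <- rbind(truth, data.frame(
              subject = subjects[si], group = spec$groups[gi],
              condition = cond, epoch_index = ep, channel = ch,
              true_K = length(regs),
              true_dwell_s = sim$truth$mean_dwell_samples / spec$fs,
              n_switches = length(sim$truth$switch_times) - 1L))
          }
          if (!is.null(spec$mixing)) dat <- spec$mixing %*% dat
          rec <- epoch_record(dat, spec$fs, subjects[si], spec$groups[gi],
                              cond, ep, age = age)
          epochs[[length(epochs) + 1L]] <- rec
          manifest <- rbind(manifest, data.frame(
            subject = subjects[si], group = spec$groups[gi], age = age,
            condition = cond, epoch_index = ep))
        }
      }
    }
  }
  list(epochs = epochs, manifest = manifest, truth = truth, spec = spec)
}
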