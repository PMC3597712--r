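#' Canonical synthetic study scenarios
#'
#' Three cohort configurations used throughout the package's validation
#' analyses, mirroring a longitudinal developmental design (three visits,
#' two resting conditions):
#'
#' * `age_effect`: the number of regimes K rises 2, 3, 4 across visits on
#'   three focal channels (a localized effect), while the mean dwell time
#'   falls 2.0, 1.5, 1.0 s on every channel (a global effect). 12 subjects,
#'   8 channels, 24 s epochs at 256 Hz, 10% observation noise.
#' * `null`: same shape, no effect anywhere (K = 2, dwell 1.5 s for all
#'   visits).
#' * `spectral_coupling`: the age-effect structure plus (i) a 2.5 Hz
#'   narrowband component on every channel whose amplitude grows with the
#'   switch rate and (ii) focal-channel regimes that are 10 Hz oscillators
#'   differing only in amplitude, so state count and alpha power rise
#'   together on focal channels. Per-subject dwell jitter decouples segment
#'   duration from state count within groups. 10 subjects, 6 channels.
#'
#' @param scenario One of `"age_effect"`, `"null"`, `"spectral_coupling"`.
#' @param seed Integer seed for the cohort.
#' @return A [cohort_spec()].
#' @export
demo_cohort_spec <- function(scenario = c("age_effect", "null",
                                          "spectral_coupling"),
                             seed = 1L) {
  scenario <- match.arg(scenario)
  switch(scenario,
    age_effect = cohort_spec(
      n_subjects = 12, groups = c("visit1", "visit2", "visit3"),
      conditions = c("eyes_open", "eyes_closed"), n_channels = 8,
      focal_channels = 1:3, epoch_length_s = 24, fs = 256,
      regimes_by_group = c(2, 3, 4), base_regimes = 2,
      dwell_by_group = c(2, 1.5, 1), noise_frac = 0.1, seed = seed),
    null = cohort_spec(
      n_subjects = 12, groups = c("visit1", "visit2", "visit3"),
      conditions = c("eyes_open", "eyes_closed"), n_channels = 8,
      epoch_length_s = 24, fs = 256,
      regimes_by_group = c(2, 2, 2), base_regimes = 2,
      dwell_by_group = c(1.5, 1.5, 1.5), noise_frac = 0.1, seed = seed),
    spectral_coupling = cohort_spec(
      n_subjects = 12, groups = c("visit1", "visit2", "visit3"),
      conditions = c("eyes_open", "eyes_closed"), n_channels = 6,
      focal_channels = 1:3, epoch_length_s = 24, fs = 256,
      regimes_by_group = c(2, 3, 4), base_regimes = 2,
      dwell_by_group = c(2, 1.5, 1), dwell_jitter_sd = 0.3,
      noise_frac = 0.1, couple_switch_to_slow = TRUE,
      focal_amplitude_states = TRUE, focal_k_jitter = TRUE, seed = seed))
}
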