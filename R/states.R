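#' Glue adjacent same-state windows into quasi-stationary segments
#'
#' Maximal runs of equal window labels are merged. A run of `k` windows on a
#' half-overlapping grid spans `(k - 1) * step + window_len` samples, i.e.
#' each glued segment's full temporal support including the overlap
#' hang-over at its ends.
#'
#' @param labels Per-window state labels, in temporal order.
#' @param grid The [segment_series()] grid the labels refer to.
#' @param fs Sampling rate, Hz.
#' @return Object of class `state_sequence` with `runs` (one row per glued
#'   segment: state, first/last window, n_windows, duration in samples and
#'   seconds, 0-based start sample) plus the inputs.
#' @export
glue_segments <- function(labels, grid, fs) {
  if (length(labels) == 0L) stop("empty label sequence")
  stopifnot(inherits(grid, "segment_grid"),
            length(labels) == grid$n_windows, fs > 0)
  r <- rle(as.vector(labels))
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  dur <- (r$lengths - 1L) * grid$step + grid$window_len
  runs <- data.frame(state = r$values, first_window = first,
                     last_window = last, n_windows = r$lengths,
                     duration_samples = dur, duration_s = dur / fs,
                     start_sample = grid$starts[first])
  structure(list(runs = runs, labels = labels, grid = grid, fs = fs),
            class = "state_sequence")
}

#' Non-stationarity measures of one epoch and channel
#'
#' The two summary measures: `n_states`, the number of distinct
#' quasi-stationary states visited in the epoch (cluster count), and
#' `mean_seg_len_s`, the mean duration in seconds of the glued
#' quasi-stationary segments.
#'
#' @param seq A [glue_segments()] result.
#' @return One-row data frame: `n_states`, `mean_seg_len_s`,
#'   `mean_seg_len_samples`, `n_runs`.
#' @export
compute_measures <- function(seq) {
  stopifnot(inherits(seq, "state_sequence"))
  data.frame(n_states = length(unique(seq$runs$state)),
             mean_seg_len_s = mean(seq$runs$duration_s),
             mean_seg_len_samples = mean(seq$runs$duration_samples),
             n_runs = nrow(seq$runs))
}

#' Average per-epoch measures across epochs
#'
#' @param per_epoch Data frame of per-epoch measures for one subject,
#'   condition and channel, with columns `subject`, `condition`, `channel`,
#'   `n_states`, `mean_seg_len_s`.
#' @return One-row data frame with the arithmetic means and `n_epochs`.
#' @export
average_over_epochs <- function(per_epoch) {
  stopifnot(nrow(per_epoch) >= 1)
  for (key in intersect(c("subject", "group", "condition", "channel"),
                        names(per_epoch)))
    if (length(unique(per_epoch[[key]])) != 1L)
      stop("cannot average across different values of '", key, "'")
  out <- per_epoch[1L, setdiff(names(per_epoch),
                               c("n_states", "mean_seg_len_s",
                                 "mean_seg_len_samples", "n_runs",
                                 "epoch_index")), drop = FALSE]
  out$n_states <- mean(per_epoch$n_states)
  out$mean_seg_len_s <- mean(per_epoch$mean_seg_len_s)
  out$n_epochs <- nrow(per_epoch)
  rownames(out) <- NULL
  out
}

#' Full non-stationarity analysis of one channel
#'
#' Segments the signal, fits the polynomial map per window, clusters windows
#' by coefficient distance with two-stage affinity propagation, glues
#' adjacent same-state windows and computes the two measures.
#'
#' @param x Single-channel sample vector (epoch mean already removed).
#' @param fs Sampling rate, Hz.
#' @param config An [analysis_config()].
#' @return List with `grid`, `models`, `clustering`, `sequence` and
#'   `measures`.
#' @export
channel_nonstat <- function(x, fs, config = analysis_config()) {
  grid <- segment_series(x, config$window_len, config$overlap_fraction)
  models <- fit_segment_models(x, grid, config$m, config$p, config$ridge,
                               normalize = isTRUE(config$normalize_segments))
  D <- distance_matrix(models)
  cl <- two_stage_cluster(D, damping = config$damping,
                          max_iter = config$max_iter,
                          conv_window = config$conv_window,
                          seed = config$seed)
  seq <- glue_segments(cl$labels, grid, fs)
  list(grid = grid, models = models, clustering = cl, sequence = seq,
       measures = compute_measures(seq))
}

#' Non-stationarity measures for a whole cohort
#'
#' Runs [channel_nonstat()] on every channel of every epoch, then averages
#' across epochs within subject, group, condition and channel. Gluing never
#' crosses epoch boundaries: every epoch is analysed on its own.
#'
#' @param epochs List of [epoch_record()] objects.
#' @param config An [analysis_config()].
#' @param keep_details Also return per-window coefficient and assignment
#'   tables across all epochs and channels (window starts 0-based).
#' @return List with `averaged` (one row per subject x group x condition x
#'   channel: the epoch-averaged `n_states` and `mean_seg_len_s`) and
#'   `per_epoch` (one row per epoch and channel); with `keep_details`,
#'   additionally `coefs` and `assignments`.
#' @export
cohort_measures <- function(epochs, config = analysis_config(),
                            keep_details = FALSE) {
  rows <- vector("list", length(epochs))
  coef_rows <- list()
  assign_rows <- list()
  for (i in seq_along(epochs)) {
    ep <- epochs[[i]]
    ch_rows <- lapply(seq_len(nrow(ep$data)), function(ch) {
      res <- channel_nonstat(ep$data[ch, ], ep$fs, config)
      if (keep_details) {
        key <- data.frame(subject = ep$subject, group = ep$group,
                          condition = ep$condition,
                          epoch_index = ep$epoch_index,
                          channel = ep$channel_names[ch],
                          window = seq_len(res$grid$n_windows) - 1L,
                          start = res$grid$starts)
        cf <- as.data.frame(res$models$coefs)
        names(cf) <- paste0("a", seq_len(ncol(cf)))
        coef_rows[[length(coef_rows) + 1L]] <<- cbind(key, cf)
        assign_rows[[length(assign_rows) + 1L]] <<- cbind(
          key,
          end = res$grid$starts + res$grid$window_len,
          stage1_label = if (is.null(res$clustering$stage1))
            res$clustering$labels else
            match(res$clustering$stage1$labels,
                  res$clustering$stage1$exemplars) - 1L,
          final_label = res$clustering$labels,
          exemplar = seq_len(res$grid$n_windows) %in%
            res$clustering$exemplars,
          degenerate = res$models$degenerate)
      }
      cbind(data.frame(subject = ep$subject, group = ep$group,
                       age = ep$age, condition = ep$condition,
                       epoch_index = ep$epoch_index,
                       channel = ep$channel_names[ch]),
            res$measures)
    })
    rows[[i]] <- do.call(rbind, ch_rows)
  }
  per_epoch <- do.call(rbind, rows)
  key <- interaction(per_epoch$subject, per_epoch$group,
                     per_epoch$condition, per_epoch$channel, drop = TRUE)
  averaged <- do.call(rbind, lapply(split(per_epoch, key),
                                    average_over_epochs))
  averaged <- averaged[order(averaged$subject, averaged$group,
                             averaged$condition, averaged$channel), ]
  rownames(averaged) <- NULL
  out <- list(averaged = averaged, per_epoch = per_epoch)
  if (keep_details) {
    out$coefs <- do.call(rbind, coef_rows)
    out$assignments <- do.call(rbind, assign_rows)
  }
  out
}
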