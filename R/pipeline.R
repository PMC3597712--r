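#' Segmentation and clustering settings
#'
#' Tunable parameters of the per-channel analysis with their defaults:
#' half-overlapping windows of 128 samples; a map over the `m = 3` most
#' recent values with polynomial order `p = 1` (higher orders are supported
#' and used where a nonlinear regime is expected; the low default keeps the
#' coefficient-estimation variance at the default window length well below
#' the between-regime coefficient separation); a numerically invisible ridge;
#' affinity-propagation damping 0.9.
#'
#' @param window_len Window length, samples.
#' @param overlap_fraction Window overlap (0.5 = half-overlapping).
#' @param m,p Embedding dimension and polynomial order of the map model.
#' @param ridge Ridge penalty on the normal equations.
#' @param normalize_segments Z-score each window before fitting (off by
#'   default; see [fit_segment_models()]).
#' @param damping,max_iter,conv_window Affinity-propagation settings.
#' @param seed Seed for any stochastic step (none by default).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(window_len = 128L, overlap_fraction = 0.5,
                            m = 3L, p = 1L, ridge = 1e-8,
                            normalize_segments = FALSE,
                            damping = 0.9, max_iter = 1000L,
                            conv_window = 50L, seed = 1L) {
  structure(list(window_len = as.integer(window_len),
                 overlap_fraction = overlap_fraction,
                 m = as.integer(m), p = as.integer(p), ridge = ridge,
                 normalize_segments = normalize_segments,
                 damping = damping, max_iter = as.integer(max_iter),
                 conv_window = as.integer(conv_window),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Full run configuration
#'
#' Materialises every default so a run is reproducible from its saved
#' config alone. Sections: `segmentation`, `clustering`, `resampling`,
#' `spectra`, `paths`.
#'
#' @param segmentation,clustering,resampling,spectra,paths Named lists
#'   overriding individual defaults.
#' @return Object of class `run_config`.
#' @export
run_config <- function(segmentation = list(), clustering = list(),
                       resampling = list(), spectra = list(),
                       paths = list()) {
  merge_section <- function(defaults, given) {
    bad <- setdiff(names(given), names(defaults))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "))
    defaults[names(given)] <- given
    defaults
  }
  cfg <- list(
    segmentation = merge_section(list(window_len = 128L,
                                      overlap_fraction = 0.5, m = 3L,
                                      p = 1L, ridge = 1e-8,
                                      normalize_segments = FALSE),
                                 segmentation),
    clustering = merge_section(list(damping = 0.9, max_iter = 1000L,
                                    conv_window = 50L), clustering),
    resampling = merge_section(list(n_perm = 500L, n_boot = 500L,
                                    seed = 1L), resampling),
    spectra = merge_section(list(band = c(1, 30), window_s = 2), spectra),
    paths = merge_section(list(manifest = NULL, out_dir = NULL), paths))
  structure(cfg, class = "run_config")
}

validate_run_config <- function(config) {
  if (!inherits(config, "run_config")) {
    required <- c("segmentation", "clustering", "resampling", "spectra",
                  "paths")
    missing <- setdiff(required, names(config))
    if (length(missing))
      stop("config is missing section(s): ", paste(missing, collapse = ", "))
  }
  config
}

as_analysis_config <- function(config) {
  analysis_config(window_len = config$segmentation$window_len,
                  overlap_fraction = config$segmentation$overlap_fraction,
                  m = config$segmentation$m, p = config$segmentation$p,
                  ridge = config$segmentation$ridge,
                  normalize_segments = config$segmentation$normalize_segments,
                  damping = config$clustering$damping,
                  max_iter = config$clustering$max_iter,
                  conv_window = config$clustering$conv_window,
                  seed = config$resampling$seed)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

write_output_table <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# config_hash: ", hash),
               "# sample and window indices are 0-based"), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a table written by [run_pipeline()]
#'
#' @param path Output file with `#` header lines.
#' @return Data frame.
#' @export
read_output_table <- function(path) {
  utils::read.delim(path, comment.char = "#")
}

#' Run the full analysis pipeline
#'
#' From a cohort manifest (synthetic or real) to non-stationarity measures,
#' PLS summaries and spectral partial-correlation maps, written to a run
#' directory with stage subdirectories. All outputs carry the config hash.
#'
#' @param config A [run_config()] whose `paths` section names the cohort
#'   `manifest` and an `out_dir`.
#' @param contrasts Optional named list of cell-by-q contrast matrices for
#'   contrast PLS (e.g. `list(age = linear_trend_contrast(...))`); if
#'   `NULL`, a linear group trend is used when there are 3 or more groups.
#' @return Invisibly, a list with the measures tables, PLS results,
#'   correlation maps and the run log.
#' @export
run_pipeline <- function(config, contrasts = NULL) {
  config <- validate_run_config(config)
  if (is.null(config$paths$manifest) || is.null(config$paths$out_dir))
    stop("config$paths must name 'manifest' and 'out_dir'")
  t0 <- Sys.time()
  hash <- config_hash(config)
  out <- config$paths$out_dir
  for (d in c("", "measures", "pls", "spectra"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null", pretty = TRUE),
             file.path(out, "config.json"))

  epochs <- read_epochs(config$paths$manifest)
  acfg <- as_analysis_config(config)
  dir.create(file.path(out, "fits"), showWarnings = FALSE)
  meas <- cohort_measures(epochs, acfg, keep_details = TRUE)
  write_output_table(meas$per_epoch,
                     file.path(out, "measures", "per_epoch.tsv"), hash)
  write_output_table(meas$averaged,
                     file.path(out, "measures", "averaged.tsv"), hash)
  write_output_table(meas$coefs,
                     file.path(out, "fits", "window_coefs.tsv"), hash)
  write_output_table(meas$assignments,
                     file.path(out, "fits", "assignments.tsv"), hash)
  writeLines(jsonlite::toJSON(
    list(m = acfg$m, p = acfg$p, window_len = acfg$window_len,
         step = as.integer(round(acfg$window_len *
                                   (1 - acfg$overlap_fraction))),
         ridge = acfg$ridge,
         normalize_segments = acfg$normalize_segments,
         coordinate_convention = "0-based half-open windows"),
    auto_unbox = TRUE, pretty = TRUE),
    file.path(out, "fits", "sidecar.json"))

  groups <- unique(meas$averaged$group)
  conditions <- unique(meas$averaged$condition)
  if (is.null(contrasts) && length(groups) >= 3L)
    contrasts <- list(age = linear_trend_contrast(groups, conditions))
  rs <- config$resampling
  pls_rows <- NULL
  bsr_tables <- list()
  pls_results <- list()
  for (measure in c("n_states", "mean_seg_len_s")) {
    pd <- pls_data(meas$averaged, measure)
    runs <- list(list(mode = "mean_centered", design = NULL,
                      name = paste0(measure, "_mean_centered")))
    for (nm in names(contrasts))
      runs <- c(runs, list(list(mode = "contrast", design = contrasts[[nm]],
                                name = paste0(measure, "_contrast_", nm))))
    for (run in runs) {
      fit <- refit_pls(pd$X, pd$meta, run$mode, run$design)
      pt <- permutation_test(pd$X, pd$meta, run$mode, run$design,
                             n_perm = rs$n_perm, seed = rs$seed)
      bs <- bootstrap_ratios(pd$X, pd$meta, run$mode, run$design,
                             n_boot = rs$n_boot, seed = rs$seed + 1L)
      pls_rows <- rbind(pls_rows, data.frame(
        analysis = run$name, lv = seq_along(fit$d), singular_value = fit$d,
        perm_p = pt$perm_p))
      bsr <- data.frame(channel = pd$channels, bs$bsr)
      names(bsr)[-1] <- paste0("lv", seq_len(ncol(bs$bsr)))
      bsr_tables[[run$name]] <- bsr
      write_output_table(bsr, file.path(out, "pls",
                                        paste0("bsr_", run$name, ".tsv")),
                         hash)
      pls_results[[run$name]] <- list(fit = fit, perm = pt, boot = bs)
    }
  }
  write_output_table(pls_rows, file.path(out, "pls", "summary.tsv"), hash)

  power <- do.call(rbind, lapply(epochs, relative_power,
                                 band = config$spectra$band,
                                 window_s = config$spectra$window_s))
  power_avg <- average_power_over_epochs(power)
  cors <- list()
  for (measure in c("n_states", "mean_seg_len_s")) {
    cors[[measure]] <- power_nonstat_correlation(meas$averaged, power_avg,
                                                 measure)
    write_output_table(cors[[measure]],
                       file.path(out, "spectra",
                                 paste0("partial_corr_", measure, ".tsv")),
                       hash)
  }

  log <- list(config_hash = hash, n_epochs = length(epochs),
              n_channels = nrow(epochs[[1]]$data),
              started = format(t0), finished = format(Sys.time()),
              elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
              r_version = R.version.string,
              package_version = as.character(utils::packageVersion("dynstates")))
  writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE),
             file.path(out, "run_log.json"))
  invisible(list(measures = meas, pls_summary = pls_rows, pls = pls_results,
                 bsr = bsr_tables, correlations = cors, log = log,
                 config_hash = hash))
}
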