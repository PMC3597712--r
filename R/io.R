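#' Write a cohort to disk
#'
#' One tab-separated matrix file per epoch (rows are samples, columns are
#' channels, header row of channel names), a cohort manifest, and a
#' ground-truth sidecar table. Sample indices are 0-based throughout the
#' package's file formats.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  manifest$fs <- vapply(cohort$epochs, `[[`, numeric(1), "fs")
  manifest$file <- sprintf("epoch_%03d.tsv", seq_along(cohort$epochs))
  for (i in seq_along(cohort$epochs)) {
    ep <- cohort$epochs[[i]]
    m <- t(ep$data)
    colnames(m) <- ep$channel_names
    utils::write.table(m, file.path(dir, manifest$file[i]), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}

read_epoch_matrix <- function(path) {
  m <- utils::read.delim(path, check.names = FALSE)
  t(as.matrix(m))
}

#' Read a cohort manifest into epoch records
#'
#' Loads every epoch file referenced by a [write_cohort()] manifest. Files
#' ending in `.edf` are read through the EDF adapter; anything else is read
#' as a delimited sample-by-channel matrix.
#'
#' @param manifest_path Path to `manifest.tsv`.
#' @param demean Subtract each channel's epoch mean on load.
#' @return List of [epoch_record()] objects.
#' @export
read_epochs <- function(manifest_path, demean = TRUE) {
  manifest <- utils::read.delim(manifest_path)
  if (nrow(manifest) == 0L) stop("empty manifest: ", manifest_path)
  dir <- dirname(manifest_path)
  epochs <- vector("list", nrow(manifest))
  n_ch <- list()
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, manifest$file[i])
    if (!file.exists(path)) stop("epoch file not found: ", path)
    if (grepl("\\.edf$", path, ignore.case = TRUE)) {
      edf <- read_edf(path)
      dat <- edf$data
      fs <- edf$fs
      ch <- edf$channel_names
    } else {
      dat <- read_epoch_matrix(path)
      fs <- manifest$fs[i]
      ch <- rownames(dat)
    }
    s <- as.character(manifest$subject[i])
    if (!is.null(n_ch[[s]]) && n_ch[[s]] != nrow(dat))
      stop("channel count mismatch for subject ", s)
    n_ch[[s]] <- nrow(dat)
    epochs[[i]] <- epoch_record(dat, fs, manifest$subject[i],
                                manifest$group[i], manifest$condition[i],
                                manifest$epoch_index[i],
                                age = if ("age" %in% names(manifest))
                                  manifest$age[i] else NA_real_,
                                channel_names = ch, demean = demean)
  }
  epochs
}

pad_field <- function(x, width) {
  x <- as.character(x)
  formatC(substr(x, 1L, width), width = width, flag = "-")
}

#' Write an epoch as a minimal EDF file
#'
#' European Data Format, one data record spanning the whole epoch, 16-bit
#' samples scaled per channel to the physical min/max of the data. Intended
#' for interchange and round-trip testing of the EDF adapter, not as a full
#' EDF+ implementation.
#'
#' @param epoch An [epoch_record()].
#' @param path Output path.
#' @export
write_edf <- function(epoch, path) {
  dat <- epoch$data
  ns <- nrow(dat)
  n_samp <- ncol(dat)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_field("0", 8), pad_field(epoch$subject, 80),
                pad_field("dynstates", 80), pad_field("01.01.00", 8),
                pad_field("00.00.00", 8),
                pad_field(256 + 256 * ns, 8), pad_field("", 44),
                pad_field(1, 8), pad_field(n_samp / epoch$fs, 8),
                pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  pmin_ <- apply(dat, 1, min)
  pmax_ <- apply(dat, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  fields <- c(list(pad_field(epoch$channel_names, 16)),
              list(pad_field("", 80)), list(pad_field("au", 8)),
              list(pad_field(sprintf("%.8g", pmin_), 8)),
              list(pad_field(sprintf("%.8g", pmax_), 8)),
              list(pad_field(-32768, 8)), list(pad_field(32767, 8)),
              list(pad_field("", 80)), list(pad_field(n_samp, 8)),
              list(pad_field("", 32)))
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32)
  for (j in seq_along(fields)) {
    f <- fields[[j]]
    f <- rep_len(f, ns)
    writeChar(paste0(f, collapse = ""), con, eos = NULL)
  }
  for (ch in seq_len(ns)) {
    dig <- round((dat[ch, ] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) * 65535 -
                   32768)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a minimal EDF file
#'
#' @param path Path to an EDF file as written by [write_edf()] (single data
#'   record; 16-bit little-endian samples).
#' @return List with `data` (channel by sample matrix), `fs`,
#'   `channel_names`, `subject`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)
  subject <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  chn <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  dat <- matrix(0, ns, nsamp[1] * n_rec)
  for (r in seq_len(n_rec)) for (ch in seq_len(ns)) {
    dig <- readBin(con, "integer", nsamp[ch], size = 2, endian = "little")
    phys <- pmin_[ch] + (dig - dmin_[ch]) / (dmax_[ch] - dmin_[ch]) *
      (pmax_[ch] - pmin_[ch])
    dat[ch, ((r - 1) * nsamp[ch] + 1):(r * nsamp[ch])] <- phys
  }
  rownames(dat) <- chn
  list(data = dat, fs = nsamp[1] / rec_dur, channel_names = chn,
       subject = subject)
}
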