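# File interfaces: a minimal EDF (European Data Format) writer/reader
# for signal exchange, delimited-text feature tables and manifests with
# lossless numeric round-trip, and run-config serialization.

pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write signals to an EDF file
#'
#' Standard EDF: 16-bit samples, one-second data records. Each signal is
#' scaled to its own physical range, so the quantization step is
#' (max - min) / 65535.
#'
#' @param signals numeric matrix, samples x signals.
#' @param fs sampling rate, Hz (integer; samples per data record).
#' @param labels signal labels (<= 16 characters).
#' @param path output file.
#' @param units physical dimension string per signal (default "uV").
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, labels, path, units = "uV") {
  signals <- as.matrix(signals)
  ns <- ncol(signals)
  fs <- as.integer(round(fs))
  n_rec <- nrow(signals) %/% fs
  if (n_rec < 1) reject("less than one data record", "affectpipe_bad_input")
  units <- rep_len(units, ns)
  pmin_ <- apply(signals, 2L, min)
  pmax_ <- apply(signals, 2L, max)
  flat <- pmax_ == pmin_
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8), pad(1, 8),
    pad(ns, 4),
    paste(vapply(labels, pad, "", width = 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(vapply(units, pad, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", pmin_), pad, "", width = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", pmax_), pad, "", width = 8), collapse = ""),
    paste(rep(pad(-32768, 8), ns), collapse = ""),
    paste(rep(pad(32767, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  dig <- vapply(seq_len(ns), function(j) {
    as.integer(round((signals[, j] - pmin_[j]) / (pmax_[j] - pmin_[j]) *
                       65535 - 32768))
  }, integer(nrow(signals)))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(as.vector(dig[idx, ])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any 16-bit EDF with a
#' common sampling rate across signals)
#'
#' @param path EDF file.
#' @return list: `signals` (samples x signals matrix, physical units),
#'   `fs`, `labels`, `units`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    reject("mixed per-signal rates not supported", "affectpipe_bad_input")
  }
  fs <- spr[1] / rec_dur
  sig <- matrix(0, n_rec * spr[1], ns, dimnames = list(NULL, labels))
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2L,
                     endian = "little")
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    sig[idx, ] <- matrix(block, spr[1], ns)
  }
  for (j in seq_len(ns)) {
    sig[, j] <- pmin_[j] + (sig[, j] - dmin[j]) *
      (pmax_[j] - pmin_[j]) / (dmax[j] - dmin[j])
  }
  list(signals = sig, fs = fs, labels = labels, units = units)
}

#' Write a dataset's signal windows and manifest to a directory
#'
#' One EDF per subject-stimulus (10 signals: 9 EEG channels + ECG) plus
#' a delimited-text manifest with ids, scores, labels, seed and
#' ground-truth columns.
#'
#' @param dataset an `affect_dataset`.
#' @param dir output directory (created if needed).
#' @return manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- dataset$manifest
  manifest$edf_path <- NA_character_
  for (i in seq_along(dataset$records)) {
    rec <- dataset$records[[i]]
    fn <- sprintf("%s_stim%02d.edf", rec$subject_id, rec$stimulus_id)
    n <- min(nrow(rec$eeg$signals), length(rec$ecg$samples))
    write_edf(cbind(rec$eeg$signals[seq_len(n), ],
                    ECG = rec$ecg$samples[seq_len(n)]),
              fs = rec$eeg$fs, labels = c(rec$eeg$labels, "ECG"),
              path = file.path(dir, fn))
    manifest$edf_path[i] <- fn
  }
  mp <- file.path(dir, "manifest.csv")
  write_feature_table(manifest, mp)
  invisible(mp)
}

#' Write a table with lossless numeric representation
#'
#' Numeric columns are rendered with 17 significant digits so that
#' reading the file back reproduces the doubles bit-exactly.
#'
#' @param df data frame.
#' @param path output CSV path.
#' @export
write_feature_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table written by [write_feature_table()]
#' @param path CSV path.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Serialize / parse a run configuration
#'
#' Plain `key = value` text; `read_run_config(write_run_config(cfg))`
#' reproduces the configuration exactly.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  vals <- vapply(config, function(v) {
    if (is.character(v)) v
    else if (is.logical(v)) as.character(v)
    else if (is.integer(v)) sprintf("%dL", v)
    else sprintf("%.17g", v)
  }, "")
  writeLines(paste(names(config), vals, sep = " = "), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  out <- stats::setNames(lapply(kv, function(p) {
    v <- p[2]
    if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else if (grepl("^-?[0-9]+L$", v)) as.integer(sub("L$", "", v))
    else if (grepl("^[-0-9.eE+]+$", v)) as.numeric(v)
    else v
  }), vapply(kv, `[`, "", 1))
  structure(out, class = "run_config")
}
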