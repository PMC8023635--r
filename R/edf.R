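# Minimal EDF/EDF+ codec for continuous clinical recordings.
#
# Supports the common clinical case this package targets: uninterrupted
# recordings in which every signal shares one sampling rate. Signals are
# stored as 16-bit integers with a per-signal physical calibration range;
# round-tripping is therefore exact up to that quantization.

EDF_LABEL_SYNONYMS <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Normalize clinical EDF channel labels to montage conventions
#'
#' Strips `"EEG "` prefixes and reference suffixes (e.g. `"-REF"`), matches
#' case-insensitively against the built-in montage labels, and applies the
#' old/new 10/20 temporal-chain synonym map (T3/T7, T4/T8, T5/P7, T6/P8).
#' Labels with no montage counterpart (e.g. mastoids `A1`/`A2`/`M1`/`M2`)
#' are kept verbatim so they can be excluded by montage subsetting later.
#'
#' @param labels character vector of raw EDF signal labels.
#' @return character vector of normalized labels.
#' @export
normalize_channel_labels <- function(labels) {
  lab <- trimws(labels)
  lab <- sub("^EEG[ _]+", "", lab, ignore.case = TRUE)
  lab <- sub("-(REF|LE|AVG|A1|A2|M1|M2)$", "", lab, ignore.case = TRUE)
  lab <- trimws(lab)
  up <- toupper(lab)
  syn <- match(up, names(EDF_LABEL_SYNONYMS))
  lab[!is.na(syn)] <- EDF_LABEL_SYNONYMS[syn[!is.na(syn)]]
  canonical <- hd91_layout()$label
  hit <- match(toupper(lab), toupper(canonical))
  lab[!is.na(hit)] <- canonical[hit[!is.na(hit)]]
  lab
}

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' @param rec an `eeg_recording` (signals in microvolts).
#' @param path output file path.
#' @param record_s data-record duration in seconds (default 1).
#' @return `path`, invisibly. Trailing samples that do not fill a whole data
#'   record are dropped (at most `record_s` seconds).
#' @export
write_edf <- function(rec, path, record_s = 1) {
  fs <- rec$sampling_rate
  spr <- round(fs * record_s)
  if (abs(spr - fs * record_s) > 1e-9)
    stop_eegprog("record_s * sampling_rate must be integer", class = "eegprog_invalid")
  n_ch <- nrow(rec$signals)
  n_rec <- floor(ncol(rec$signals) / spr)
  if (n_rec < 1)
    stop_eegprog("recording shorter than one data record", class = "eegprog_invalid")
  x <- rec$signals[, seq_len(n_rec * spr), drop = FALSE]

  # symmetric physical range per channel, padded to avoid clipping
  pmax_ <- apply(abs(x), 1, max)
  pmax_ <- ifelse(pmax_ <= 0, 1, pmax_ * 1.0001)
  dig_min <- -32768L; dig_max <- 32767L
  scale <- (2 * pmax_) / (dig_max - dig_min)
  dig <- round(sweep(sweep(x, 1, pmax_, "+"), 1, scale, "/")) + dig_min
  dig[dig > dig_max] <- dig_max
  dig[dig < dig_min] <- dig_min
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * n_ch
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8), edf_pad(hdr_bytes, 8),
    edf_pad("", 44), edf_pad(n_rec, 8), edf_pad(format(record_s), 8),
    edf_pad(n_ch, 4)), con, eos = NULL)
  fld <- function(v, w) writeChar(paste(edf_pad(v, w), collapse = ""), con, eos = NULL)
  fld(rec$channel_labels, 16)
  fld(rep("", n_ch), 80)
  fld(rep("uV", n_ch), 8)
  fld(formatC(-pmax_, digits = 5, format = "g"), 8)
  fld(formatC(pmax_, digits = 5, format = "g"), 8)
  fld(rep(dig_min, n_ch), 8)
  fld(rep(dig_max, n_ch), 8)
  fld(rep("", n_ch), 80)
  fld(rep(spr, n_ch), 8)
  fld(rep("", n_ch), 32)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into a recording
#'
#' All signals must share one sampling rate (the clinical layout this
#' package analyses); annotation channels are dropped. Channel labels are
#' normalized via [normalize_channel_labels()].
#'
#' @param path EDF file path.
#' @param montage_ref montage name to attach (default `"ld1020"`).
#' @return An `eeg_recording` with signals in the file's physical units
#'   (microvolts for clinical EEG).
#' @export
read_edf <- function(path, montage_ref = "ld1020") {
  if (!file.exists(path))
    stop_eegprog("EDF file not found: %s", path, class = "eegprog_format")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    if (length(raw) < w) stop_eegprog("truncated EDF header in %s", path,
                                      class = "eegprog_format")
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  if (!startsWith(version, "0"))
    stop_eegprog("not an EDF file (version field '%s'): %s", version, path,
                 class = "eegprog_format")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                        # header bytes (recomputed below)
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  record_s <- suppressWarnings(as.numeric(rd(8)))
  n_sig <- suppressWarnings(as.integer(rd(4)))
  if (is.na(n_rec) || is.na(record_s) || is.na(n_sig) || n_sig < 1)
    stop_eegprog("malformed EDF header: %s", path, class = "eegprog_format")
  rdv <- function(w) vapply(seq_len(n_sig), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)

  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (!any(keep)) stop_eegprog("no data signals in %s", path, class = "eegprog_format")
  if (length(unique(spr[keep])) != 1L)
    stop_eegprog("signals with mismatched sampling rates in %s (unsupported layout)",
                 path, class = "eegprog_unsupported_layout")
  fs <- spr[keep][1] / record_s
  n_per <- sum(spr)
  dat <- readBin(con, "integer", n = n_per * n_rec, size = 2L,
                 endian = "little", signed = TRUE)
  if (length(dat) < n_per * n_rec)
    stop_eegprog("truncated EDF data in %s", path, class = "eegprog_format")
  sig_idx <- rep.int(seq_len(n_sig), spr)
  out <- matrix(0, sum(keep), sum(spr[keep]) / sum(keep) * n_rec)
  ki <- which(keep)
  for (s in seq_along(ki)) {
    i <- ki[s]
    sel <- which(rep(sig_idx, n_rec) == i)
    d <- dat[sel]
    g <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    out[s, ] <- (d - dig_min[i]) * g + phys_min[i]
  }
  new_recording(out, fs, normalize_channel_labels(labels[ki]),
                montage_ref = montage_ref)
}
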