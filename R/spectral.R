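# Power spectra and relative band power.
#
# Canonical bands: delta [0.5, 4), theta [4, 8), alpha [8, 13]. The delta
# floor sits at the 0.5 Hz high-pass edge because bins below the filter
# cut-off carry roll-off, not signal. Band intervals are half-open at the
# top except alpha (inclusive), so the shared 4 and 8 Hz bins are never
# counted twice.

#' Canonical frequency band definition
#'
#' @param name band name.
#' @param lo,hi band edges, Hz.
#' @param hi_inclusive whether the upper edge bin is included.
#' @return list of class `band_definition`.
#' @export
band_definition <- function(name, lo, hi, hi_inclusive = FALSE) {
  if (lo >= hi) stop_eegprog("band needs lo < hi", class = "eegprog_invalid")
  structure(list(name = name, lo = lo, hi = hi, hi_inclusive = hi_inclusive),
            class = "band_definition")
}

#' Default delta/theta/alpha band definitions
#' @return named list of `band_definition`s.
#' @export
default_bands <- function() {
  list(delta = band_definition("delta", 0.5, 4),
       theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13, hi_inclusive = TRUE))
}

band_bins <- function(freqs, band) {
  sel <- freqs >= band$lo &
    (if (band$hi_inclusive) freqs <= band$hi else freqs < band$hi)
  which(sel)
}

#' Welch power spectral density of epoched EEG
#'
#' Per channel: 2-s Hamming-tapered segments with 50% overlap, periodograms
#' averaged within and across epochs; one-sided density in uV^2/Hz on a
#' 0.5 Hz grid restricted to the analysed range `[0.5, 45]` Hz.
#'
#' @param ep an `eeg_epochs` object (>= 1 epoch).
#' @param seg_s Welch segment length in seconds (default 2).
#' @param fmin,fmax retained frequency range, Hz.
#' @return Object of class `eeg_spectrum`: list with `psd`
#'   (channels x frequencies), `freqs` and `n_epochs_used`.
#' @export
compute_psd <- function(ep, seg_s = 2, fmin = 0.5, fmax = 45) {
  d <- dim(ep$epochs)
  fs <- ep$sampling_rate
  nseg <- round(seg_s * fs)
  if (nseg > d[3])
    stop_eegprog("Welch segment (%d samples) longer than epoch (%d)", nseg, d[3],
                 class = "eegprog_invalid")
  step <- nseg %/% 2
  w <- signal::hamming(nseg)
  u <- sum(w^2)
  starts <- seq(1, d[3] - nseg + 1, by = step)
  nf <- nseg %/% 2 + 1
  freqs <- (0:(nf - 1)) * fs / nseg
  acc <- matrix(0, d[2], nf)
  n_avg <- 0L
  for (e in seq_len(d[1])) {
    for (s0 in starts) {
      seg <- ep$epochs[e, , s0:(s0 + nseg - 1), drop = TRUE]
      if (is.null(dim(seg))) seg <- matrix(seg, nrow = d[2])
      seg <- sweep(seg, 2, w, `*`)
      X <- t(stats::mvfft(t(seg)))[, seq_len(nf), drop = FALSE]
      p <- (Mod(X)^2) / (fs * u)
      p[, 2:(nf - 1)] <- 2 * p[, 2:(nf - 1)]   # one-sided
      acc <- acc + p
      n_avg <- n_avg + 1L
    }
  }
  psd <- acc / n_avg
  keep <- freqs >= fmin & freqs <= fmax
  structure(list(psd = psd[, keep, drop = FALSE], freqs = freqs[keep],
                 channel_labels = ep$channel_labels, n_epochs_used = d[1]),
            class = "eeg_spectrum")
}

#' Relative band power per channel
#'
#' Trapezoidal integral of the PSD over the band divided by the integral
#' over the full analysed range.
#'
#' @param spec an `eeg_spectrum`.
#' @param band a `band_definition` inside the spectrum's range.
#' @return numeric vector in `[0, 1]`, one value per channel.
#' @export
relative_band_power <- function(spec, band) {
  f <- spec$freqs
  if (band$lo < min(f) || band$hi > max(f))
    stop_eegprog("band [%g, %g] outside analysed range [%g, %g]",
                 band$lo, band$hi, min(f), max(f), class = "eegprog_invalid")
  bins <- band_bins(f, band)
  if (length(bins) < 2)
    stop_eegprog("band [%g, %g] covers fewer than 2 frequency bins",
                 band$lo, band$hi, class = "eegprog_invalid")
  total <- apply(spec$psd, 1, function(p) trapz(f, p))
  if (any(total <= 0))
    stop_eegprog("zero total power on channel(s): %s",
                 paste(spec$channel_labels[total <= 0], collapse = ", "),
                 class = "eegprog_invalid")
  inband <- apply(spec$psd[, bins, drop = FALSE], 1,
                  function(p) trapz(f[bins], p))
  out <- inband / total
  names(out) <- spec$channel_labels
  out
}

#' Mean of a per-channel feature over channels
#' @param per_channel numeric vector (non-empty).
#' @return scalar mean.
#' @export
mean_relative_power <- function(per_channel) {
  if (!length(per_channel))
    stop_eegprog("empty per-channel vector", class = "eegprog_invalid")
  mean(per_channel)
}
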