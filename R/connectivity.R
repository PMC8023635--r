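# Debiased weighted phase lag index (dwPLI) connectivity.
#
# Phase-lag-index estimators use only the imaginary part of the
# cross-spectrum, which is blind to zero-lag (volume-conduction / common
# reference) coupling. The debiased squared-WPLI estimator corrects the
# small-sample positive bias of WPLI^2 and can therefore be slightly
# negative under the null. One observation = one epoch per frequency bin;
# the per-bin debiased estimates are averaged over the bins within a band.

upper_pairs <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(2:n, function(k) k:n))
  cbind(i = i, j = j)
}

#' Epoch-wise cross-spectra of all channel pairs within a band
#'
#' Per epoch, each channel is Hanning-tapered and Fourier transformed over
#' the full epoch (frequency resolution 1/epoch-length); the cross-spectrum
#' `Z = X_a * Conj(X_b)` is collected at every bin inside the band.
#'
#' @param ep an `eeg_epochs` object (>= 2 epochs).
#' @param band a `band_definition` inside `[0.5, 45]` Hz.
#' @return complex array `[pairs x epochs x bins]` with attributes `pairs`
#'   (upper-triangle index matrix), `channel_labels`, `band` and `freqs`.
#' @export
epoch_cross_spectra <- function(ep, band) {
  d <- dim(ep$epochs)
  if (d[1] < 2)
    stop_eegprog("need >= 2 epochs for cross-spectral observations",
                 class = "eegprog_invalid")
  if (band$lo < 0.5 || band$hi > 45)
    stop_eegprog("band [%g, %g] outside the analysed range [0.5, 45] Hz",
                 band$lo, band$hi, class = "eegprog_invalid")
  fs <- ep$sampling_rate
  ns <- d[3]
  w <- signal::hanning(ns)
  freqs <- (0:(ns %/% 2)) * fs / ns
  bins <- band_bins(freqs, band)
  if (!length(bins))
    stop_eegprog("no frequency bins inside band [%g, %g]", band$lo, band$hi,
                 class = "eegprog_invalid")
  pairs <- upper_pairs(d[2])
  out <- array(complex(real = 0), dim = c(nrow(pairs), d[1], length(bins)))
  for (e in seq_len(d[1])) {
    seg <- sweep(ep$epochs[e, , , drop = TRUE], 2, w, `*`)
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = d[2])
    X <- t(stats::mvfft(t(seg)))[, bins, drop = FALSE]   # channels x bins
    out[, e, ] <- X[pairs[, "i"], , drop = FALSE] *
      Conj(X[pairs[, "j"], , drop = FALSE])
  }
  attr(out, "pairs") <- pairs
  attr(out, "channel_labels") <- ep$channel_labels
  attr(out, "band") <- band
  attr(out, "freqs") <- freqs[bins]
  out
}

#' Debiased weighted phase lag index from cross-spectral observations
#'
#' With `I_k = Im(Z_k)` over the `K` observations (epochs) of one pair and
#' bin, the debiased squared WPLI is
#' `((sum I)^2 - sum I^2) / ((sum |I|)^2 - sum I^2)`, defined as 0 when the
#' denominator vanishes, then averaged over the band's bins.
#'
#' @param observations output of [epoch_cross_spectra()].
#' @return Object of class `connectivity_matrix`: list with symmetric
#'   `values` (zero diagonal, entries <= 1, possibly slightly negative),
#'   `band`, `channel_labels` and `n_observations` (epochs).
#' @export
dwpli <- function(observations) {
  d <- dim(observations)
  if (d[2] < 2)
    stop_eegprog("dwPLI needs >= 2 observations (epochs)", class = "eegprog_invalid")
  I <- aperm(Im(observations), c(2, 1, 3))    # epochs x pairs x bins
  s1 <- colSums(I)                            # pairs x bins
  s2 <- colSums(I^2)
  s3 <- colSums(abs(I))
  num <- s1^2 - s2
  den <- s3^2 - s2
  est <- ifelse(den == 0, 0, num / den)       # pairs x bins
  per_pair <- rowMeans(est)
  labels <- attr(observations, "channel_labels")
  n <- length(labels)
  values <- matrix(0, n, n, dimnames = list(labels, labels))
  pairs <- attr(observations, "pairs")
  values[pairs] <- per_pair
  values[pairs[, c(2, 1), drop = FALSE]] <- per_pair
  structure(list(values = values, band = attr(observations, "band"),
                 channel_labels = labels, n_observations = d[2]),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s band, %d channels, %d epochs; median dwPLI = %.3f\n",
              x$band$name, length(x$channel_labels), x$n_observations,
              median_connectivity(x)))
  invisible(x)
}

#' Median connectivity over channel pairs
#'
#' Median of the strict upper triangle (each unordered pair counted once).
#'
#' @param cm a `connectivity_matrix`.
#' @return scalar.
#' @export
median_connectivity <- function(cm) {
  v <- cm$values
  if (nrow(v) < 2)
    stop_eegprog("need >= 2 channels", class = "eegprog_invalid")
  stats::median(v[upper.tri(v)])
}

#' dwPLI matrices for a set of bands
#'
#' Convenience wrapper running [epoch_cross_spectra()] + [dwpli()] per band.
#' @param ep an `eeg_epochs` object.
#' @param bands named list of `band_definition`s (default alpha and delta).
#' @return named list of `connectivity_matrix` objects.
#' @export
band_connectivity <- function(ep, bands = default_bands()[c("alpha", "delta")]) {
  lapply(bands, function(b) dwpli(epoch_cross_spectra(ep, b)))
}

#' Export a connectivity matrix as CSV (labels as header row/column)
#' @param cm a `connectivity_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(cm$values), path, row.names = TRUE)
  invisible(path)
}
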