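# Shared small simulation fixtures (built in code at test time).

quick_recording <- function(seed = 1, duration_s = 60, montage = "ld1020",
                            ...) {
  simulate_eeg(eeg_sim_spec(duration_s = duration_s, montage_ref = montage,
                            seed = seed, ...))
}

two_module_assignment <- function(montage = "ld1020") {
  labels <- load_montage(montage)$labels
  stats::setNames(rep(1:2, length.out = length(labels)), labels)
}

sine_recording <- function(freq, fs = 256, duration_s = 10, n_ch = 2,
                           amplitude = 50) {
  t <- seq_len(duration_s * fs) / fs
  x <- matrix(rep(amplitude * sin(2 * pi * freq * t), n_ch), nrow = n_ch,
              byrow = TRUE)
  new_recording(x, fs, LD1020_LABELS_TEST[seq_len(n_ch)], "ld1020")
}

LD1020_LABELS_TEST <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                        "T7", "C3", "Cz", "C4", "T8",
                        "P7", "P3", "Pz", "P4", "P8", "O1", "O2")

# Synthetic healthy high-density subjects used by the reliability
# experiments (two designs, both with per-subject alpha level and coupling):
#
# * "ring": one global module whose channel copies step around a phase ring
#   (k * 45 degrees) - strong, reliable band power and median dwPLI; used by
#   the cross-montage validation experiment.
# * "wedge": 2-5 spatially contiguous azimuthal wedge modules per subject -
#   distinct, subject-specific modular geometry; used by the recording-length
#   reliability experiment where the graph features are under test.

hd_ring_recording <- function(k, seed, duration_s = 300) {
  m <- load_montage("hd91")
  ma <- stats::setNames(rep(1L, length(m$labels)), m$labels)
  simulate_eeg(eeg_sim_spec(duration_s = duration_s, montage_ref = "hd91",
                            band_profiles = c(delta = 0.25, theta = 0.05,
                                              alpha = 0.15 + 0.5 * (k - 1) / 19),
                            module_assignment = ma,
                            coupled_band = c("alpha", "delta"),
                            coupling = 0.2 + 0.75 * (k - 1) / 19,
                            lag_deg = 45, mixing = 0.2, seed = seed))
}

hd_wedge_recording <- function(k, seed, duration_s = 600) {
  m <- load_montage("hd91")
  az <- atan2(m$coordinates[, 2], m$coordinates[, 1])
  n_mod <- 2 + (k - 1) %% 4
  ma <- stats::setNames(as.integer(cut(rank(az, ties.method = "first"),
                                       n_mod, labels = FALSE)), m$labels)
  simulate_eeg(eeg_sim_spec(duration_s = duration_s, montage_ref = "hd91",
                            band_profiles = c(delta = 0.25, theta = 0.05,
                                              alpha = 0.15 + 0.5 * (k - 1) / 19),
                            module_assignment = ma,
                            coupled_band = c("alpha", "delta"),
                            coupling = 0.5 + 0.45 * (k - 1) / 19,
                            lag_deg = 45, mixing = 0.2, seed = seed))
}
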