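# Synthetic EEG and synthetic cohorts.
#
# The generator produces multichannel EEG whose statistical structure
# matches what the analysis pipeline assumes: narrowband oscillations with
# controllable relative band power, phase-lagged modular coupling that a
# phase-lag-index estimator can detect, zero-lag spatial mixing emulating
# volume conduction, and a 1/f broadband background. Sources sit at the
# electrodes (one per channel) rather than in a volume-conduction head
# model, which is sufficient to exercise every estimator while keeping the
# generator auditable.

#' Specification of a synthetic EEG recording
#'
#' @param duration_s recording length, seconds.
#' @param sampling_rate Hz.
#' @param montage_ref montage name (`"ld1020"` or `"hd91"`).
#' @param band_profiles named numeric vector of relative-power weights for
#'   `delta`, `theta`, `alpha`; must sum to <= 1 (the remainder goes to the
#'   1/f background).
#' @param module_assignment optional named integer vector (channel -> module
#'   id) imposing modular coupling in `coupled_band`.
#' @param coupled_band band(s) carrying the modular coupling (default alpha;
#'   may name several bands, each of which then gets its own set of
#'   phase-lagged drivers with the same module assignment and coupling).
#' @param coupling fraction `c` in `[0, 1]` of within-module source variance
#'   contributed by a shared phase-lagged driver.
#' @param lag_deg phase-lag step between driver copies, degrees; the k-th
#'   channel of a module (sorted-label order, 0-based) receives the driver
#'   rotated by `k * lag_deg` via analytic-signal rotation.
#' @param mixing zero-lag spatial mixing strength `m` in `[0, 1)`:
#'   `x <- (1 - m) x + m W x` with Gaussian spatial weights `W`.
#' @param mixing_sigma spatial scale of the mixing kernel, head-radius units.
#' @param noise_1f_weight broadband 1/f background weight (default: the
#'   remainder `1 - sum(band_profiles)`).
#' @param amplitude_uV overall signal scale, microvolts RMS.
#' @param seed integer RNG seed.
#' @return list of class `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(duration_s = 300, sampling_rate = 128,
                         montage_ref = "ld1020",
                         band_profiles = c(delta = 0.25, theta = 0.1, alpha = 0.35),
                         module_assignment = NULL, coupled_band = "alpha",
                         coupling = 0, lag_deg = 45, mixing = 0,
                         mixing_sigma = 0.5, noise_1f_weight = NULL,
                         amplitude_uV = 20, seed = 1L) {
  if (sum(band_profiles) > 1 + 1e-12)
    stop_eegprog("band_profiles must sum to <= 1", class = "eegprog_invalid")
  if (coupling < 0 || coupling > 1)
    stop_eegprog("coupling must be in [0, 1]", class = "eegprog_invalid")
  if (mixing < 0 || mixing >= 1)
    stop_eegprog("mixing must be in [0, 1)", class = "eegprog_invalid")
  if (duration_s < 10)
    stop_eegprog("duration must cover at least one 10-s epoch", class = "eegprog_invalid")
  noise_1f_weight <- noise_1f_weight %||% max(1 - sum(band_profiles), 0)
  structure(list(duration_s = duration_s, sampling_rate = sampling_rate,
                 montage_ref = montage_ref, band_profiles = band_profiles,
                 module_assignment = module_assignment,
                 coupled_band = coupled_band, coupling = coupling,
                 lag_deg = lag_deg, mixing = mixing,
                 mixing_sigma = mixing_sigma,
                 noise_1f_weight = noise_1f_weight,
                 amplitude_uV = amplitude_uV, seed = as.integer(seed)),
            class = "eeg_sim_spec")
}

band_edges_for <- function(name) {
  b <- default_bands()[[name]]
  c(b$lo, b$hi)
}

# narrowband unit-variance noise: white noise through a zero-phase
# Butterworth band-pass (4th order per edge); rows = independent channels
narrowband_noise_mat <- function(n_ch, n, fs, lo, hi) {
  y <- fft_bandpass(matrix(stats::rnorm(n_ch * n), n_ch), fs, lo, hi, order = 4)
  y / apply(y, 1, stats::sd)
}

narrowband_noise <- function(n, fs, lo, hi) {
  drop(narrowband_noise_mat(1, n, fs, lo, hi))
}

# white noise shaped to 1/f amplitude, unit variance; rows = channels
pink_noise_mat <- function(n_ch, n) {
  X <- stats::mvfft(matrix(stats::rnorm(n_ch * n), n, n_ch))
  k <- 0:(n - 1)
  f <- pmax(pmin(k, n - k), 1)    # symmetric two-sided frequency index
  X <- X / f
  X[1, ] <- 0
  y <- t(Re(stats::mvfft(X, inverse = TRUE)) / n)
  y / apply(y, 1, stats::sd)
}

rotate_phase <- function(x, deg) {
  if (deg %% 360 == 0) return(x)
  Re(analytic_signal(x) * exp(1i * deg * pi / 180))
}

rotate_analytic <- function(a, deg) Re(a * exp(1i * deg * pi / 180))

#' Simulate a multichannel EEG recording
#'
#' Per band, narrowband Gaussian sources are made by band-pass filtering
#' white noise. Within the coupled band, the source of the k-th channel of a
#' module (0-based, sorted-label order) is
#' `sqrt(c) * rotate(driver_m, k * lag_deg) + sqrt(1-c) * independent noise`.
#' Each channel is a weighted sum of its band sources and a 1/f background,
#' then zero-lag spatial mixing `x <- (1-m) x + m W x` is applied.
#' Deterministic given `spec$seed`.
#'
#' @param spec an `eeg_sim_spec`.
#' @return An `eeg_recording` on the spec's montage.
#' @export
simulate_eeg <- function(spec) {
  m <- load_montage(spec$montage_ref)
  n_ch <- length(m$labels)
  fs <- spec$sampling_rate
  n <- round(spec$duration_s * fs)
  with_seed(spec$seed, {
    x <- matrix(0, n_ch, n)
    for (bname in names(spec$band_profiles)) {
      wgt <- spec$band_profiles[[bname]]
      if (wgt <= 0) next
      e <- band_edges_for(bname)
      lo <- max(e[1], 0.5)
      if (!is.null(spec$module_assignment) && bname %in% spec$coupled_band &&
          spec$coupling > 0) {
        src <- matrix(0, n_ch, n)
        mods <- spec$module_assignment[m$labels]
        if (anyNA(mods))
          stop_eegprog("module_assignment must cover every montage channel",
                       class = "eegprog_invalid")
        for (mod in sort(unique(mods))) {
          driver_a <- analytic_signal(narrowband_noise(n, fs, lo, e[2]))
          ch <- which(mods == mod)
          ch <- ch[order(m$labels[ch])]
          indep <- narrowband_noise_mat(length(ch), n, fs, lo, e[2])
          for (k in seq_along(ch)) {
            shared <- rotate_analytic(driver_a, (k - 1) * spec$lag_deg)
            s <- sqrt(spec$coupling) * shared +
              sqrt(1 - spec$coupling) * indep[k, ]
            src[ch[k], ] <- s / stats::sd(s)
          }
        }
      } else {
        src <- narrowband_noise_mat(n_ch, n, fs, lo, e[2])
      }
      x <- x + sqrt(wgt) * src
    }
    if (spec$noise_1f_weight > 0)
      x <- x + sqrt(spec$noise_1f_weight) * pink_noise_mat(n_ch, n)
    if (spec$mixing > 0) {
      d <- as.matrix(stats::dist(m$coordinates))
      W <- exp(-d^2 / (2 * spec$mixing_sigma^2))
      diag(W) <- 0
      W <- W / rowSums(W)
      x <- (1 - spec$mixing) * x + spec$mixing * (W %*% x)
    }
    x <- x * spec$amplitude_uV
    new_recording(x, fs, m$labels, montage_ref = spec$montage_ref)
  })
}

#' Inject a high-amplitude spike artifact (test helper)
#'
#' @param rec an `eeg_recording`.
#' @param at_s spike time, seconds.
#' @param channel channel label (default first).
#' @param amplitude_uV spike amplitude (default 500).
#' @param width_s spike width, seconds.
#' @return The modified `eeg_recording`.
#' @export
inject_spikes <- function(rec, at_s, channel = rec$channel_labels[1],
                          amplitude_uV = 500, width_s = 0.1) {
  i <- match(channel, rec$channel_labels)
  if (is.na(i))
    stop_eegprog("unknown channel '%s'", channel, class = "eegprog_missing_channel")
  fs <- rec$sampling_rate
  k0 <- round(at_s * fs)
  w <- round(width_s * fs)
  idx <- pmin(pmax(k0:(k0 + w), 1), ncol(rec$signals))
  bump <- amplitude_uV * exp(-((seq_along(idx) - w / 2)^2) / (2 * (w / 4)^2))
  rec$signals[i, idx] <- rec$signals[i, idx] + bump
  rec
}

#' Specification of a synthetic patient cohort
#'
#' Outcome model: latent health
#' `h = effect_gcs * z(gcs) + effect_alpha * z(alpha_target) + N(0, noise_sd)`,
#' thresholded at `gose_cutpoints` to GOSE 1-8. Each patient's EEG alpha
#' weight is `plogis(alpha_target)` (scaled into the free weight budget), so
#' extracted mean relative alpha power increases with `alpha_target`.
#'
#' @param n_patients number of patients (>= 3).
#' @param effect_gcs standardized slope of the latent outcome on total GCS.
#' @param effect_alpha standardized slope on the latent alpha level.
#' @param noise_sd residual SD of the latent outcome.
#' @param gose_cutpoints strictly increasing length-7 thresholds; default:
#'   equal-probability normal quantiles of the latent scale.
#' @param seed integer RNG seed.
#' @return list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_patients = 18, effect_gcs = 0.7,
                            effect_alpha = 0.4, noise_sd = 0.6,
                            gose_cutpoints = NULL, seed = 1L) {
  if (n_patients < 3)
    stop_eegprog("need n_patients >= 3", class = "eegprog_invalid")
  if (is.null(gose_cutpoints)) {
    latent_sd <- sqrt(effect_gcs^2 + effect_alpha^2 + noise_sd^2)
    gose_cutpoints <- stats::qnorm((1:7) / 8) * latent_sd
  }
  if (length(gose_cutpoints) != 7 || any(diff(gose_cutpoints) <= 0))
    stop_eegprog("gose_cutpoints must be strictly increasing, length 7",
                 class = "eegprog_invalid")
  structure(list(n_patients = as.integer(n_patients), effect_gcs = effect_gcs,
                 effect_alpha = effect_alpha, noise_sd = noise_sd,
                 gose_cutpoints = gose_cutpoints, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

zscore <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0

#' Simulate a patient cohort with paired EEG recordings
#'
#' Clinical variables: age ~ Uniform{18..90}, GCS ~ Uniform{3..11} (patients
#' below command-following), CT grade ~ Uniform{1..6}, days since injury ~
#' Uniform{3..24}, sex male with probability 0.8. GOSE at 3 months comes from
#' the latent health model; GOSE at 6 months re-thresholds the latent value
#' plus extra noise (`noise_sd / 2`). Deterministic given `spec$seed`.
#'
#' @param spec a `cohort_sim_spec`.
#' @param eeg_template an `eeg_sim_spec` template; each patient's alpha band
#'   weight is replaced by `plogis(alpha_target)` scaled into the weight
#'   budget left by the other bands, and the seed is re-drawn per patient.
#' @param simulate_recordings if `FALSE`, return the table only (recordings
#'   list empty).
#' @return list with `cohort` (a `cohort_table` including the latent
#'   `alpha_target` column) and `recordings` (list of `eeg_recording`).
#' @export
simulate_cohort <- function(spec, eeg_template = eeg_sim_spec(),
                            simulate_recordings = TRUE) {
  n <- spec$n_patients
  with_seed(spec$seed, {
    age <- sample(18:90, n, replace = TRUE)
    gcs <- sample(3:11, n, replace = TRUE)
    ct <- sample(1:6, n, replace = TRUE)
    days <- sample(3:24, n, replace = TRUE)
    sex <- ifelse(stats::runif(n) < 0.8, "male", "female")
    alpha_target <- stats::rnorm(n)
    h3 <- spec$effect_gcs * zscore(gcs) + spec$effect_alpha * zscore(alpha_target) +
      stats::rnorm(n, 0, spec$noise_sd)
    h6 <- h3 + stats::rnorm(n, 0, spec$noise_sd / 2)
    to_gose <- function(h) 1L + vapply(h, function(v) sum(spec$gose_cutpoints < v), 0L)
    eeg_seeds <- sample.int(.Machine$integer.max - 1L, n)
    cohort <- data.frame(id = as.character(seq_len(n)), sex = sex,
                         age_years = age, ct_grade = ct,
                         days_since_injury = days, gcs_total = gcs,
                         gose_3mo = to_gose(h3), gose_6mo = to_gose(h6),
                         alpha_target = alpha_target,
                         stringsAsFactors = FALSE)
    validate_cohort(cohort)
    recordings <- list()
    if (simulate_recordings) {
      other <- sum(eeg_template$band_profiles[setdiff(names(eeg_template$band_profiles), "alpha")])
      recordings <- lapply(seq_len(n), function(i) {
        s <- eeg_template
        s$band_profiles[["alpha"]] <- stats::plogis(alpha_target[i]) * (1 - other)
        s$noise_1f_weight <- max(1 - sum(s$band_profiles), 0)
        s$seed <- eeg_seeds[i]
        simulate_eeg(s)
      })
      names(recordings) <- cohort$id
    }
    list(cohort = cohort, recordings = recordings)
  })
}
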