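# Cross-montage feature reliability.
#
# Features are computed twice per subject: once from the full high-density
# montage and once from the 10/20 channel subset taken BEFORE preprocessing,
# so the low-density path is processed exactly like clinical data (the
# average reference, in particular, differs between paths). Features whose
# low-density estimates significantly track the high-density estimates are
# selected for clinical use. The same association machinery generalizes to
# the 10-minute versus 5-minute recording-length reliability check.

#' Paired association between two per-subject feature vectors
#'
#' Shapiro-Wilk normality is tested on each vector; if either marginal
#' departs from normality (p < 0.05) the association is Spearman's rank
#' correlation, otherwise Pearson's. Two-tailed p-value; `selected` flags
#' `p < alpha_level`.
#'
#' @param x,y numeric vectors of equal length >= 4, no missing values.
#' @param alpha_level selection threshold (default 0.05).
#' @param feature label carried into the result.
#' @return one-row data frame: `feature`, `method`, `coefficient`,
#'   `p_value`, `normality_p_x`, `normality_p_y`, `selected`.
#' @export
paired_feature_association <- function(x, y, alpha_level = 0.05,
                                       feature = "feature") {
  if (length(x) != length(y) || length(x) < 4)
    stop_eegprog("need equal-length vectors with n >= 4", class = "eegprog_invalid")
  if (anyNA(x) || anyNA(y))
    stop_eegprog("missing values not allowed", class = "eegprog_invalid")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_eegprog("constant input vector: correlation undefined for '%s'",
                 feature, class = "eegprog_invalid")
  sw_x <- stats::shapiro.test(x)$p.value
  sw_y <- stats::shapiro.test(y)$p.value
  method <- if (sw_x < 0.05 || sw_y < 0.05) "spearman" else "pearson"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  data.frame(feature = feature, method = method,
             coefficient = unname(ct$estimate), p_value = ct$p.value,
             normality_p_x = sw_x, normality_p_y = sw_y,
             selected = ct$p.value < alpha_level,
             stringsAsFactors = FALSE)
}

features_for_recording <- function(rec, montage, seed, n_runs = 100, ...) {
  ep <- preprocess(rec, ...)
  extract_features(ep, montage, seed = seed, n_runs = n_runs)
}

#' Cross-montage feature validation
#'
#' For each subject the full pipeline (preprocess then feature extraction)
#' is run independently on the high-density montage and on the low-density
#' channel subset taken before preprocessing; each of the eight features is
#' then associated across subjects between the two paths.
#'
#' @param recordings list of high-density `eeg_recording`s (all containing
#'   the low-density channels).
#' @param hd_montage,ld_montage `eeg_montage` objects (low-density labels
#'   must be a subset of each recording's channels).
#' @param seed integer seed for community detection.
#' @param n_runs Louvain restarts.
#' @param alpha_level selection threshold.
#' @param ... preprocessing arguments passed to [preprocess()].
#' @return list with `results` (8-row data frame), `selected` (character),
#'   `hd_features` and `ld_features` (subjects x features matrices).
#' @export
validate_features <- function(recordings, hd_montage, ld_montage,
                              seed = 1L, n_runs = 100, alpha_level = 0.05, ...) {
  seeds <- derive_seeds(seed, length(recordings))
  hd <- ld <- NULL
  for (s in seq_along(recordings)) {
    rec <- recordings[[s]]
    f_hd <- features_for_recording(rec, hd_montage, seed = seeds[s],
                                   n_runs = n_runs, ...)
    rec_ld <- subset_channels(rec, intersect(rec$channel_labels, ld_montage$labels),
                              montage_ref = ld_montage$name)
    f_ld <- features_for_recording(rec_ld, ld_montage, seed = seeds[s],
                                   n_runs = n_runs, ...)
    hd <- rbind(hd, f_hd)
    ld <- rbind(ld, f_ld)
  }
  results <- do.call(rbind, lapply(colnames(hd), function(fn)
    paired_feature_association(hd[, fn], ld[, fn], alpha_level = alpha_level,
                               feature = fn)))
  list(results = results, selected = results$feature[results$selected],
       hd_features = hd, ld_features = ld)
}

#' Recording-length (segment) reliability of features
#'
#' Features are computed from the first `len_a_s` and the first `len_b_s`
#' seconds of each recording (full pipeline each time) and associated per
#' feature across subjects.
#'
#' @param recordings list of `eeg_recording`s at least `max(len_a_s,
#'   len_b_s)` seconds long.
#' @param len_a_s,len_b_s segment lengths in seconds (e.g. 600 vs 300).
#' @param montage an `eeg_montage` covering the channels.
#' @inheritParams validate_features
#' @return list with `results` (8-row data frame), `a_features`,
#'   `b_features`.
#' @export
segment_reliability <- function(recordings, len_a_s, len_b_s, montage,
                                seed = 1L, n_runs = 100, alpha_level = 0.05, ...) {
  seeds <- derive_seeds(seed, length(recordings))
  a <- b <- NULL
  for (s in seq_along(recordings)) {
    rec <- recordings[[s]]
    a <- rbind(a, features_for_recording(crop_recording(rec, len_a_s), montage,
                                         seed = seeds[s], n_runs = n_runs, ...))
    b <- rbind(b, features_for_recording(crop_recording(rec, len_b_s), montage,
                                         seed = seeds[s], n_runs = n_runs, ...))
  }
  results <- do.call(rbind, lapply(colnames(a), function(fn)
    paired_feature_association(a[, fn], b[, fn], alpha_level = alpha_level,
                               feature = fn)))
  list(results = results, a_features = a, b_features = b)
}
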