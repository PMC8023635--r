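# Pipeline orchestration: reproducible end-to-end runs driven by a YAML
# config with seed handling and run logs. A thin command-line front-end
# (inst/cli/eegprog) exposes the same five stages as subcommands:
# simulate | features | validate-montage | cca | prognose.

#' Default pipeline configuration
#'
#' @return named list of configuration defaults: paths, preprocessing
#'   thresholds, band edges, density grid, permutation count, seeds and
#'   montage names.
#' @export
default_config <- function() {
  list(paths = list(input_dir = ".", cohort_csv = "cohort.csv", output_dir = "."),
       preprocess = list(lo_hz = 0.5, hi_hz = 45, epoch_s = 10,
                         ptp_uv = 200, z_var = 3),
       densities = seq(0.9, 0.1, by = -0.1),
       n_perm = 2000,
       n_runs = 100,
       seed = 1L,
       montage = "ld1020",
       simulate = list(n_patients = 18, duration_s = 300, sampling_rate = 128,
                       effect_gcs = 0.7, effect_alpha = 0.4, noise_sd = 0.6),
       clinical_vars = c("age_years", "gcs_total", "ct_grade", "days_since_injury"),
       outcome = "gose_3mo",
       entry_p = 0.05, removal_p = 0.10)
}

#' Read a pipeline config (YAML), merged over the defaults
#' @param path YAML file, or `NULL` for pure defaults.
#' @return config list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_eegprog("config file not found: %s", path, class = "eegprog_config")
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

write_run_log <- function(cfg, stage, out_dir, extra = list()) {
  log <- c(list(stage = stage, seed = cfg$seed, config_hash = config_hash(cfg),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  jsonlite::write_json(log, file.path(out_dir, paste0("runlog_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Stage: simulate a synthetic cohort with EDF recordings
#'
#' Writes one EDF per patient plus `cohort.csv` and a run log into
#' `cfg$paths$output_dir`.
#' @param cfg pipeline config (see [default_config()]).
#' @return invisibly, the simulated cohort table.
#' @export
run_simulate <- function(cfg = default_config()) {
  out <- cfg$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$simulate
  spec <- cohort_sim_spec(n_patients = sim$n_patients, effect_gcs = sim$effect_gcs,
                          effect_alpha = sim$effect_alpha, noise_sd = sim$noise_sd,
                          seed = cfg$seed)
  tmpl <- eeg_sim_spec(duration_s = sim$duration_s,
                       sampling_rate = sim$sampling_rate,
                       montage_ref = cfg$montage)
  res <- simulate_cohort(spec, tmpl)
  for (id in res$cohort$id)
    write_edf(res$recordings[[id]], file.path(out, paste0("patient_", id, ".edf")))
  write_cohort(res$cohort[, COHORT_COLUMNS], file.path(out, "cohort.csv"))
  write_run_log(cfg, "simulate", out, list(n_patients = nrow(res$cohort)))
  invisible(res$cohort)
}

#' Stage: extract features for every recording and merge into the cohort
#'
#' Reads `patient_<id>.edf` files from the input directory, preprocesses
#' them, extracts the eight features, writes per-recording JSON and a merged
#' cohort CSV with the feature columns appended.
#' @param cfg pipeline config.
#' @return invisibly, the merged cohort data frame.
#' @export
run_features <- function(cfg = default_config()) {
  out <- cfg$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(cfg$paths$cohort_csv)
  montage <- load_montage(cfg$montage)
  pp <- cfg$preprocess
  seeds <- derive_seeds(cfg$seed, nrow(cohort))
  feats <- NULL
  rejected <- list()
  for (k in seq_len(nrow(cohort))) {
    id <- cohort$id[k]
    path <- file.path(cfg$paths$input_dir, paste0("patient_", id, ".edf"))
    if (!file.exists(path))
      stop_eegprog("stage features: missing EDF for patient %s (%s)", id, path,
                   class = "eegprog_config")
    rec <- read_edf(path, montage_ref = cfg$montage)
    rec <- subset_channels(rec, intersect(rec$channel_labels, montage$labels))
    ep <- preprocess(rec, lo = pp$lo_hz, hi = pp$hi_hz, epoch_s = pp$epoch_s,
                     ptp_uV = pp$ptp_uv, z_var = pp$z_var)
    f <- extract_features(ep, montage, seed = seeds[k], n_runs = cfg$n_runs)
    rejected[[id]] <- ep$rejection_log
    jsonlite::write_json(as.list(f), file.path(out, paste0("features_", id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    feats <- rbind(feats, f)
  }
  merged <- cbind(as.data.frame(cohort), as.data.frame(feats))
  write_cohort(merged, file.path(out, "cohort_features.csv"))
  write_run_log(cfg, "features", out,
                list(n_recordings = nrow(cohort),
                     rejected_epochs = sum(vapply(rejected, function(r)
                       length(r$epochs), 0L)),
                     rejected_channels = sum(vapply(rejected, function(r)
                       length(r$channels), 0L))))
  invisible(merged)
}

#' Stage: CCA between clinical variables and EEG features
#'
#' @param cfg pipeline config; `cfg$paths$cohort_csv` must point to a cohort
#'   CSV containing the feature columns (see [run_features()]).
#' @param features feature columns to use (default: the eight keys present).
#' @return invisibly, the `cca_result` with loadings.
#' @export
run_cca <- function(cfg = default_config(), features = NULL) {
  out <- cfg$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(cfg$paths$cohort_csv)
  features <- features %||% intersect(feature_names(), names(cohort))
  if (!length(features))
    stop_eegprog("stage cca: no feature columns in %s", cfg$paths$cohort_csv,
                 class = "eegprog_config")
  keep <- stats::complete.cases(cohort[, c(cfg$clinical_vars, features)])
  x <- cohort[keep, cfg$clinical_vars]
  y <- cohort[keep, features]
  res <- permutation_test_cca(x, y, n_perm = cfg$n_perm, seed = cfg$seed)
  res$loadings <- variate_loadings(res, x, y)
  payload <- list(canonical_correlations = res$canonical_correlations,
                  p_values = res$p_values, n = res$n, n_perm = res$n_perm,
                  x_weights = as.data.frame(res$x_weights),
                  y_weights = as.data.frame(res$y_weights),
                  loadings_x = res$loadings$x, loadings_y = res$loadings$y,
                  cases_dropped = sum(!keep))
  jsonlite::write_json(payload, file.path(out, "cca.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  write_run_log(cfg, "cca", out, list(n_cases = res$n, cases_dropped = sum(!keep)))
  invisible(res)
}

#' Stage: stepwise prognostic regression on transformed outcome
#'
#' The outcome (GOSE) is rank-inverse-normal transformed, then stepwise
#' regression runs over the EEG features plus the clinical candidates
#' (clinical variables and sex coded 0/1).
#'
#' @param cfg pipeline config.
#' @param features candidate feature columns (default: the eight keys
#'   present in the cohort CSV).
#' @return invisibly, the `stepwise_result`.
#' @export
run_prognose <- function(cfg = default_config(), features = NULL) {
  out <- cfg$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(cfg$paths$cohort_csv)
  features <- features %||% intersect(feature_names(), names(cohort))
  clin <- cohort[, cfg$clinical_vars, drop = FALSE]
  clin$sex_male <- as.numeric(cohort$sex == "male")
  candidates <- cbind(clin, cohort[, features, drop = FALSE])
  outcome <- cohort[[cfg$outcome]]
  keep <- !is.na(outcome)
  y <- rank_inverse_normal(outcome[keep])
  res <- stepwise_regression(y, candidates[keep, , drop = FALSE],
                             entry_p = cfg$entry_p, removal_p = cfg$removal_p)
  payload <- list(outcome = cfg$outcome, selected = res$selected,
                  beta = as.list(res$beta), p_values = as.list(res$p_values),
                  adj_r_squared = res$adj_r_squared,
                  f_statistic = res$f_statistic, df = res$df,
                  model_p = res$model_p, n_used = res$n_used,
                  steps = res$steps, empty = res$empty)
  jsonlite::write_json(payload, file.path(out, "prognosis.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_log(cfg, "prognose", out, list(n_cases = res$n_used))
  invisible(res)
}

#' Stage: cross-montage validation over a directory of high-density EDFs
#'
#' @param cfg pipeline config; reads every `*.edf` in `cfg$paths$input_dir`.
#' @param hd_name,ld_name montage names (default `"hd91"` / `"ld1020"`).
#' @return invisibly, the [validate_features()] result; writes
#'   `montage_validation.csv` (feature, method, coefficient, p_value,
#'   selected).
#' @export
run_validate_montage <- function(cfg = default_config(), hd_name = "hd91",
                                 ld_name = "ld1020") {
  out <- cfg$paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- list.files(cfg$paths$input_dir, pattern = "\\.edf$", full.names = TRUE)
  if (!length(files))
    stop_eegprog("stage validate-montage: no EDF files in %s",
                 cfg$paths$input_dir, class = "eegprog_config")
  recs <- lapply(files, read_edf, montage_ref = hd_name)
  pp <- cfg$preprocess
  res <- validate_features(recs, load_montage(hd_name), load_montage(ld_name),
                           seed = cfg$seed, n_runs = cfg$n_runs,
                           lo = pp$lo_hz, hi = pp$hi_hz, epoch_s = pp$epoch_s,
                           ptp_uV = pp$ptp_uv, z_var = pp$z_var)
  utils::write.csv(res$results[, c("feature", "method", "coefficient",
                                   "p_value", "selected")],
                   file.path(out, "montage_validation.csv"), row.names = FALSE)
  write_run_log(cfg, "validate_montage", out, list(n_subjects = length(recs)))
  invisible(res)
}
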