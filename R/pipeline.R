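# End-to-end orchestration: CSV schema I/O, per-patient preprocessing ->
# cycle features -> HMM state inference with cohort-level AIC state-count
# selection -> stratified transition models, plus a run manifest.

.SCHEMA_COLS <- c("patient_id", "epoch_id", "segment_id", "hour_index",
                  "iea_count", "le_count", "n_therapy_detections",
                  "b1_charge_density_uC_cm2", "b1_frequency_hz",
                  "b1_pulse_width_us", "b1_burst_duration_ms",
                  "b2_charge_density_uC_cm2", "b2_frequency_hz",
                  "b2_pulse_width_us", "b2_burst_duration_ms",
                  "b2_active", "stim_enabled", "montage", "location")

.MONTAGES <- c("monopolar_leadtolead", "bipolar")
.LOCATIONS <- c("mesiotemporal", "neocortical")

#' Load and validate an hourly telemetry CSV
#'
#' @param path CSV file in the documented schema (see `.SCHEMA_COLS` in the
#'   source; one row per patient-hour with counts, burst-level therapy-1
#'   parameters and metadata).
#' @return Validated data.frame of hourly records.
#' @export
load_hourly_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.SCHEMA_COLS, names(df))
  if (length(missing))
    rns_stop(paste0("missing column(s): ", paste(missing, collapse = ", ")),
             "rns_schema_error")
  for (col in c("iea_count", "le_count", "n_therapy_detections")) {
    x <- df[[col]]
    bad <- which(is.na(x) | x < 0 | x != round(x))
    if (length(bad))
      rns_stop(sprintf("%s must be a nonnegative integer (rows: %s)", col,
                       paste(head(bad, 5), collapse = ", ")),
               "rns_schema_error")
  }
  if (!all(df$montage %in% .MONTAGES))
    rns_stop(paste0("unknown montage value; allowed: ",
                    paste(.MONTAGES, collapse = ", ")), "rns_schema_error")
  if (!all(df$location %in% .LOCATIONS))
    rns_stop(paste0("unknown location value; allowed: ",
                    paste(.LOCATIONS, collapse = ", ")), "rns_schema_error")
  df$b2_active <- as.logical(df$b2_active)
  df$stim_enabled <- as.logical(df$stim_enabled)
  df
}

#' Preprocess raw hourly records
#'
#' Averages the two therapy-1 bursts, applies the zeroing rule for hours
#' without detections or with stimulation disabled, and orders records
#' within patient preserving segment boundaries.
#'
#' @param records raw records in the CSV schema.
#' @return Records with averaged `charge_density`, `frequency`,
#'   `pulse_width`, `burst_duration` columns appended.
#' @export
preprocess_records <- function(records) {
  avg <- average_therapy_bursts(
    records[, c("b1_charge_density_uC_cm2", "b1_frequency_hz",
                "b1_pulse_width_us", "b1_burst_duration_ms")],
    records[, c("b2_charge_density_uC_cm2", "b2_frequency_hz",
                "b2_pulse_width_us", "b2_burst_duration_ms")],
    records$b2_active)
  out <- cbind(records, avg)
  out <- apply_zeroing_rule(out)
  concatenate_segments(out)
}

#' Analysis settings for [run_pipeline()]
#'
#' @param band_periods nominal cycle periods, hours.
#' @param n_pc number of principal components fed to the HMM.
#' @param variance_target cumulative explained-variance diagnostic target.
#' @param K_candidates HMM state counts compared by cohort AIC.
#' @param n_restarts,tol,max_iter EM settings (see [fit_gaussian_hmm()]).
#' @param seed integer seed for all stochastic steps.
#' @param min_days,min_correspondence epoch inclusion thresholds
#'   (see [apply_epoch_filters()]).
#' @param fixed_only_strata character vector of `location:montage` pairs
#'   fit without random effects and with continuous covariates (default
#'   bipolar neocortical, the low-sample configuration).
#' @param mixed_min_rows,mixed_min_patients minimum stratum size for the
#'   mixed fit; smaller strata fall back to fixed-only, and strata under
#'   50 rows are reported as not estimated.
#' @return List of class `rns_pipeline_config`.
#' @export
pipeline_config <- function(band_periods = c(24, 168, 360, 480, 720),
                            n_pc = 5, variance_target = 0.80,
                            K_candidates = c(2, 3),
                            n_restarts = 3, tol = 1e-4, max_iter = 100,
                            seed = 1L, min_days = 30,
                            min_correspondence = 0.90,
                            fixed_only_strata = "neocortical:bipolar",
                            mixed_min_rows = 200, mixed_min_patients = 2) {
  structure(list(band_periods = band_periods, n_pc = n_pc,
                 variance_target = variance_target,
                 K_candidates = K_candidates, n_restarts = n_restarts,
                 tol = tol, max_iter = max_iter, seed = as.integer(seed),
                 min_days = min_days,
                 min_correspondence = min_correspondence,
                 fixed_only_strata = fixed_only_strata,
                 mixed_min_rows = mixed_min_rows,
                 mixed_min_patients = mixed_min_patients),
            class = "rns_pipeline_config")
}

#' Run the full risk-state analysis
#'
#' Executes preprocessing, cycle-feature extraction, per-patient HMM
#' fitting over the candidate state counts, cohort-level AIC selection,
#' identifiability relabeling, posterior decoding, rank-sum state
#' validation, and per-stratum transition modelling. When `out_dir` is
#' given, writes state sequences, model JSONs, the stratum results table,
#' validation reports and a run manifest.
#'
#' @param input an `rns_cohort` (from [simulate_cohort()]) or a directory
#'   of cohort CSVs written by [write_cohort()].
#' @param config an `rns_pipeline_config`.
#' @param out_dir optional output directory.
#' @return List of class `rns_results` with per-patient models, decoded
#'   states, validation reports, the AIC table, the transition design, the
#'   per-stratum fits and their summary table, and the epoch exclusion log.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         out_dir = NULL) {
  if (inherits(input, "rns_cohort")) {
    patients <- input$patients
    epochs <- input$epochs
  } else {
    files <- list.files(input, pattern = "^P.*\\.csv$", full.names = TRUE)
    patients <- lapply(files, load_hourly_csv)
    names(patients) <- vapply(patients, function(d) d$patient_id[1], "")
    epochs <- read.csv(file.path(input, "epochs.csv"),
                       stringsAsFactors = FALSE)
  }
  filt <- apply_epoch_filters(epochs, config$min_days,
                              config$min_correspondence)
  keep_epochs <- filt$included$epoch_id
  bands <- default_bands(config$band_periods)

  per_patient <- list()
  warnings_log <- character(0)
  for (pid in names(patients)) {
    rec <- patients[[pid]]
    rec <- rec[rec$epoch_id %in% keep_epochs, , drop = FALSE]
    if (nrow(rec) == 0) next
    rec <- preprocess_records(rec)
    feats <- withCallingHandlers(
      patient_cycle_features(rec, bands, config$n_pc,
                             config$variance_target),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(pid, ": ",
                                                conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    fits <- list()
    for (K in config$K_candidates) {
      fits[[as.character(K)]] <- withCallingHandlers(
        fit_gaussian_hmm(feats$pca$scores, K,
                         n_restarts = config$n_restarts,
                         seed = config$seed, tol = config$tol,
                         max_iter = config$max_iter,
                         segments = feats$segments),
        warning = function(w) {
          warnings_log <<- c(warnings_log, paste0(pid, ": ",
                                                  conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
    }
    per_patient[[pid]] <- list(records = rec, features = feats,
                               fits = fits)
  }
  if (!length(per_patient))
    rns_stop("no patient passed the epoch filters", "rns_config_error")

  sel <- select_state_count(lapply(per_patient, `[[`, "fits"),
                            scope = "cohort")
  K <- sel$K

  all_states <- list()
  all_records <- list()
  all_categories <- list()
  for (pid in names(per_patient)) {
    pp <- per_patient[[pid]]
    model <- pp$fits[[as.character(K)]]
    dec0 <- decode_states(model, pp$features$pca$scores,
                          segments = pp$features$segments,
                          hours = pp$features$hours)
    model <- relabel_states(model, dec0$state, pp$records$le_count,
                            pp$features$shifted_phases,
                            pp$records$iea_count)
    perm <- attr(model, "permutation")
    states <- match(dec0$state, perm)
    posterior <- dec0$posterior[, perm, drop = FALSE]
    dec <- structure(list(hours = dec0$hours, state = states,
                          posterior = posterior,
                          log_likelihood = dec0$log_likelihood),
                     class = "risk_state_sequence")
    validation <- if (K == 2)
      validate_risk_states(dec, pp$records$le_count, pp$records$iea_count)
    else NULL
    per_patient[[pid]]$model <- model
    per_patient[[pid]]$states <- dec
    per_patient[[pid]]$validation <- validation
    all_states[[pid]] <- if (K == 2) states else
      as.integer(states == K) + 1L  # highest-LE state treated as high risk
    all_records[[pid]] <- pp$records
    all_categories[[pid]] <- categorize_stim_params(
      pp$records$charge_density, pp$records$frequency,
      pp$records$pulse_width, pp$records$burst_duration)
  }

  records <- do.call(rbind, all_records)
  categories <- do.call(rbind, all_categories)
  states <- unlist(all_states, use.names = FALSE)
  design <- build_transition_design(states, records, categories)

  fits <- list()
  strata <- if (nrow(design)) levels(design$stratum) else character(0)
  for (s in strata) {
    d <- design[design$stratum == s, , drop = FALSE]
    locmon <- sub(":[^:]*$", "", s)
    fixed_only <- locmon %in% config$fixed_only_strata
    mode <- if (!fixed_only &&
                length(unique(d$patient_id)) >= config$mixed_min_patients &&
                nrow(d) >= config$mixed_min_rows) "mixed" else "fixed"
    cm <- if (fixed_only) "continuous" else "categorical"
    fits[[s]] <- tryCatch(
      withCallingHandlers(
        if (mode == "mixed") fit_mixed_logistic(d, cm)
        else fit_fixed_logistic(d, cm),
        warning = function(w) {
          warnings_log <<- c(warnings_log, paste0(s, ": ",
                                                  conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) list(stratum = s, reason = conditionMessage(e)))
  }
  results_table <- summarize_stratum_fits(fits)

  results <- structure(
    list(K = K, aic_table = sel$aic_table, total_aic = sel$total_aic,
         patients = per_patient, design = design, stratum_fits = fits,
         results_table = results_table, epoch_exclusions = filt$exclusions,
         warnings = warnings_log, config = config),
    class = "rns_results")
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

#' Write a results bundle to disk
#'
#' State sequences and posteriors per patient (CSV), fitted HMMs (JSON),
#' the per-stratum results table and epoch exclusion log (CSV), and a run
#' manifest (JSON: settings, seed, package version, warnings).
#'
#' @param results an `rns_results`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(results$patients)) {
    pp <- results$patients[[pid]]
    st <- data.frame(hour_index = pp$states$hours, state = pp$states$state)
    post <- as.data.frame(pp$states$posterior)
    names(post) <- paste0("posterior_", seq_len(ncol(post)))
    write.csv(cbind(st, post),
              file.path(out_dir, paste0("states_", pid, ".csv")),
              row.names = FALSE)
    write_hmm_json(pp$model, file.path(out_dir,
                                       paste0("hmm_", pid, ".json")))
  }
  write.csv(results$results_table,
            file.path(out_dir, "stratum_results.csv"), row.names = FALSE)
  write.csv(results$aic_table, file.path(out_dir, "aic_table.csv"),
            row.names = FALSE)
  write.csv(results$epoch_exclusions,
            file.path(out_dir, "epoch_exclusions.csv"), row.names = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("rnstates")),
                   K_selected = results$K,
                   settings = unclass(results$config),
                   warnings = results$warnings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
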