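# Synthetic hourly RNS telemetry with known ground truth.
#
# The generator emulates the structure the analysis assumes: IEA counts
# carrying circadian and multidien cycles, LE counts whose hourly rate
# depends on a latent two-state seizure-risk chain coupled to cycle phase,
# programming epochs with stepwise-constant therapy-1 stimulation settings
# drawn over the evaluated parameter ranges, and configurable ground-truth
# state-dependent stimulation effects on the hourly transition log-odds.

#' Simulation configuration for a synthetic RNS telemetry cohort
#'
#' Defaults describe a realistic cohort: hourly interictal epileptiform
#' activity (IEA) counts around 41/h at baseline with a small high-state
#' bump, long-episode (LE) rates of 0.3/h (low) versus 0.8/h (high),
#' circadian plus 7/15/20/30-day cycles on the log-intensity scale with the
#' 30-day band dominant, and strong coupling of the rising phase of the
#' dominant multidien cycle to the high-risk state. The dwell parameters
#' are baseline hazards in the absence of phase forcing; with the default
#' strong coupling, transitions are phase-triggered and realized dwell
#' times come out at a few hundred hours per state (multi-day risk
#' episodes), with states phase-locked to the dominant cycle.
#'
#' @param n_patients number of patients.
#' @param hours_per_patient hours of telemetry per patient.
#' @param cycle_periods cycle periods in hours (distinct, each >= 2).
#' @param cycle_amplitudes per-band amplitude on the log-intensity scale.
#' @param cycle_phases per-band initial phase, radians (per-patient random
#'   offsets are added by [simulate_cohort()]).
#' @param iea_base_rate baseline IEA events/hour (> 0).
#' @param iea_state_bump additive log-intensity bump to IEA in the
#'   high-risk state.
#' @param le_rate_low,le_rate_high LE events/hour in the low/high state
#'   (`le_rate_high >= le_rate_low`).
#' @param state_dwell_low,state_dwell_high mean dwell times, hours (>= 1).
#' @param phase_coupling log-odds coupling of the rising phase of the
#'   coupling band to entering (or remaining in) the high-risk state;
#'   positive values make rising-phase hours high-risk-prone.
#' @param coupling_band index into `cycle_periods` of the band whose rising
#'   phase drives state transitions (default 2, the 7-day cycle).
#' @param stim_effects list with elements `low` and `high`, each a named
#'   numeric vector of ground-truth log-odds effects on next-hour
#'   *low*-state probability; names must be non-reference category codes
#'   from [stim_category_levels()].
#' @param epoch_plan list with `n_epochs` (>= 1 programming epochs, each at
#'   least 720 h once hours are split), `n_subperiods` (stepwise-constant
#'   parameter draws per epoch) and `p_midhour_change` (probability a
#'   sub-period change is programmed mid-hour, exercising the start-of-hour
#'   imputation rule).
#' @param p_stim_disabled_hour probability an hour has stimulation disabled.
#' @param detection_rate mean therapy-triggering detections per hour.
#' @param p_no_detection extra probability of a zero-detection hour.
#' @param patient_intercept_sd SD of the per-patient baseline transition
#'   log-odds shift (patient heterogeneity).
#' @param le_correspondence annotation attached to generated epochs:
#'   fraction of LEs corresponding to electrographic seizures.
#' @param seed master seed for [simulate_cohort()].
#' @return A validated list of class `rns_sim_config`.
#' @export
simulation_config <- function(n_patients = 20,
                              hours_per_patient = 8760,
                              cycle_periods = c(24, 168, 360, 480, 720),
                              cycle_amplitudes = c(0.4, 0.25, 0.15, 0.1, 0.35),
                              cycle_phases = rep(0, length(cycle_periods)),
                              iea_base_rate = 40.9,
                              iea_state_bump = 0.15,
                              le_rate_low = 0.3,
                              le_rate_high = 0.8,
                              state_dwell_low = 2000,
                              state_dwell_high = 25,
                              phase_coupling = 5,
                              coupling_band = 5,
                              stim_effects = list(low = numeric(0),
                                                  high = numeric(0)),
                              epoch_plan = list(n_epochs = 3,
                                                n_subperiods = 3,
                                                p_midhour_change = 0.5),
                              p_stim_disabled_hour = 0.12,
                              detection_rate = 6,
                              p_no_detection = 0.03,
                              patient_intercept_sd = 0.3,
                              le_correspondence = 0.95,
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              hours_per_patient = as.integer(hours_per_patient),
              cycle_periods = cycle_periods,
              cycle_amplitudes = cycle_amplitudes,
              cycle_phases = cycle_phases,
              iea_base_rate = iea_base_rate,
              iea_state_bump = iea_state_bump,
              le_rate_low = le_rate_low, le_rate_high = le_rate_high,
              state_dwell_low = state_dwell_low,
              state_dwell_high = state_dwell_high,
              phase_coupling = phase_coupling,
              coupling_band = as.integer(coupling_band),
              stim_effects = stim_effects,
              epoch_plan = epoch_plan,
              p_stim_disabled_hour = p_stim_disabled_hour,
              detection_rate = detection_rate,
              p_no_detection = p_no_detection,
              patient_intercept_sd = patient_intercept_sd,
              le_correspondence = le_correspondence,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "rns_sim_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_patients < 1 || hours_per_patient < 1)
      rns_stop("n_patients and hours_per_patient must be positive",
               "rns_config_error")
    if (any(cycle_periods < 2) || anyDuplicated(cycle_periods))
      rns_stop("cycle_periods must be distinct and each >= 2 hours",
               "rns_config_error")
    if (length(cycle_amplitudes) != length(cycle_periods) ||
        length(cycle_phases) != length(cycle_periods))
      rns_stop("cycle_amplitudes and cycle_phases must match cycle_periods",
               "rns_config_error")
    if (iea_base_rate <= 0 || le_rate_low <= 0 || le_rate_high <= 0)
      rns_stop("all rates must be strictly positive", "rns_config_error")
    if (le_rate_high < le_rate_low)
      rns_stop("le_rate_high must be >= le_rate_low", "rns_config_error")
    if (state_dwell_low < 1 || state_dwell_high < 1)
      rns_stop("dwell times must be >= 1 hour", "rns_config_error")
    if (coupling_band < 1 || coupling_band > length(cycle_periods))
      rns_stop("coupling_band must index a cycle period", "rns_config_error")
    if (!is.list(stim_effects) ||
        !all(c("low", "high") %in% names(stim_effects)))
      rns_stop("stim_effects must be a list with elements 'low' and 'high'",
               "rns_config_error")
    bad <- setdiff(unlist(lapply(stim_effects, names)), .nonref_categories())
    if (length(bad))
      rns_stop(paste0("unknown stim_effects categories: ",
                      paste(bad, collapse = ", ")), "rns_config_error")
    if (is.null(epoch_plan$n_epochs) || epoch_plan$n_epochs < 1)
      rns_stop("epoch_plan must define at least one epoch",
               "rns_config_error")
    if (p_stim_disabled_hour < 0 || p_stim_disabled_hour > 1)
      rns_stop("p_stim_disabled_hour must lie in [0, 1]", "rns_config_error")
  })
  invisible(cfg)
}

#' Deterministic per-band cycle log-intensity components
#'
#' Component for band b at hour t is
#' `amplitude_b * sin(2 * pi * t / period_b + phase_b)`.
#'
#' @param config an `rns_sim_config`.
#' @param n_hours number of hours (t = 1..n_hours).
#' @return Numeric matrix, `n_hours` rows by one column per band.
#' @export
simulate_cycle_intensity <- function(config, n_hours) {
  stopifnot(n_hours >= 1)
  if (any(config$cycle_periods <= 0))
    rns_stop("cycle periods must be positive", "rns_config_error")
  t <- seq_len(n_hours)
  comp <- mapply(function(P, A, phi) A * sin(2 * pi * t / P + phi),
                 config$cycle_periods, config$cycle_amplitudes,
                 config$cycle_phases)
  comp <- matrix(comp, nrow = n_hours)
  colnames(comp) <- paste0("band_", config$cycle_periods)
  comp
}

# Baseline transition log-odds implied by mean dwell times:
# P(low next | low) is the stay probability 1 - 1/dwell_low;
# P(low next | high) is the leave probability 1/dwell_high.
.baseline_logodds <- function(config) {
  c(low = qlogis(1 - 1 / config$state_dwell_low),
    high = qlogis(1 / config$state_dwell_high))
}

# Per-hour summed ground-truth stimulation effect for a given current
# state, from the four category columns of `categories`.
.stim_effect_series <- function(categories, effects) {
  if (!length(effects)) return(numeric(nrow(categories)))
  out <- numeric(nrow(categories))
  for (col in names(categories)) {
    v <- as.character(categories[[col]])
    hit <- v %in% names(effects)
    out[hit] <- out[hit] + effects[v[hit]]
  }
  out
}

#' Simulate the latent risk-state chain
#'
#' Draws the next-hour state from a logistic model on the current state:
#' `logit P(low at t+1) = baseline(current) - phase_coupling * rising(t) +
#' patient_intercept + sum of configured effects for (current state,
#' hour-t parameter categories)`, where `rising(t)` indicates the rising phase of the coupling band and the
#' baseline terms are the logit stay/leave probabilities implied by the
#' configured mean dwell times. Positive `phase_coupling` therefore couples
#' the rising phase to the high-risk state.
#'
#' @param config an `rns_sim_config`.
#' @param cycle_components matrix from [simulate_cycle_intensity()].
#' @param stim_schedule data.frame of per-hour parameter categories as
#'   returned by [categorize_stim_params()] (aligned to the same hours).
#' @param seed integer seed.
#' @param patient_intercept additive patient-level shift on the transition
#'   log-odds (default 0).
#' @return List with `states` (integer vector, 1 = low, 2 = high) and
#'   `ground_truth` (latent states, the transition log-odds used, and the
#'   per-band cycle log-intensity).
#' @export
simulate_state_chain <- function(config, cycle_components, stim_schedule,
                                 seed, patient_intercept = 0) {
  n <- nrow(cycle_components)
  if (nrow(stim_schedule) != n)
    rns_stop("stim_schedule and cycle_components must cover the same hours",
             "rns_dimension_error")
  comp <- cycle_components[, config$coupling_band]
  rising <- c(diff(comp) > 0, FALSE)
  if (n > 1) rising[n] <- rising[n - 1]
  b <- .baseline_logodds(config)
  eff_low <- .stim_effect_series(stim_schedule, config$stim_effects$low)
  eff_high <- .stim_effect_series(stim_schedule, config$stim_effects$high)

  set.seed(seed)
  u0 <- runif(1)
  u <- runif(n - 1)
  p_low_stat <- config$state_dwell_low /
    (config$state_dwell_low + config$state_dwell_high)
  states <- integer(n)
  states[1] <- if (u0 < p_low_stat) 1L else 2L
  for (t in seq_len(n - 1)) {
    cur <- states[t]
    eta <- (if (cur == 1L) b[["low"]] + eff_low[t]
            else b[["high"]] + eff_high[t]) -
      config$phase_coupling * rising[t] + patient_intercept
    states[t + 1] <- if (u[t] < plogis(eta)) 1L else 2L
  }
  list(states = states,
       ground_truth = list(
         latent_states = states,
         true_transition_logodds = list(baseline = b,
                                        phase_coupling = config$phase_coupling,
                                        patient_intercept = patient_intercept,
                                        stim_effects = config$stim_effects),
         cycle_log_intensity = cycle_components))
}

#' Simulate hourly IEA and LE counts
#'
#' IEA counts are Poisson with log intensity
#' `log(iea_base_rate) + sum of cycle components + iea_state_bump * high`;
#' LE counts are Poisson at `le_rate_low` or `le_rate_high` by state.
#'
#' @param states integer states (1 = low, 2 = high).
#' @param cycle_components matrix from [simulate_cycle_intensity()].
#' @param config an `rns_sim_config`.
#' @param seed integer seed.
#' @return data.frame with `iea_count` and `le_count`.
#' @export
simulate_counts <- function(states, cycle_components, config, seed) {
  n <- length(states)
  if (nrow(cycle_components) != n)
    rns_stop("states and cycle_components must be aligned",
             "rns_dimension_error")
  set.seed(seed)
  lam_iea <- exp(log(config$iea_base_rate) + rowSums(cycle_components) +
                   config$iea_state_bump * (states == 2L))
  lam_le <- ifelse(states == 2L, config$le_rate_high, config$le_rate_low)
  data.frame(iea_count = rpois(n, lam_iea), le_count = rpois(n, lam_le))
}

# One draw of a therapy-1 parameter set over the evaluated ranges.
.draw_param_set <- function() {
  cd_cat <- sample(7, 1, prob = c(0.25, 0.35, 0.12, 0.08, 0.06, 0.06, 0.08))
  cd <- switch(cd_cat,
               runif(1, 0.3, 0.5), runif(1, 0.6, 3), runif(1, 3.05, 4),
               runif(1, 4.05, 5), runif(1, 5.05, 6), runif(1, 6.05, 7),
               runif(1, 7.05, 9))
  fq_cat <- sample(6, 1, prob = c(0.40, 0.10, 0.15, 0.10, 0.10, 0.15))
  fq <- switch(fq_cat,
               200, sample(c(4, 10, 20), 1), runif(1, 25, 95), 100,
               runif(1, 105, 195), sample(c(250, 333.3), 1))
  pw_cat <- sample(3, 1, prob = c(0.6, 0.2, 0.2))
  pw <- switch(pw_cat, 160, sample(c(80, 120), 1), sample(c(200, 240), 1))
  bd_cat <- sample(4, 1, prob = c(0.45, 0.07, 0.25, 0.23))
  bd <- switch(bd_cat, 100, sample(c(10, 50), 1), runif(1, 150, 500),
               sample(c(1000, 2000, 5000), 1))
  c(charge_density = cd, frequency = fq, pulse_width = pw,
    burst_duration = bd)
}

#' Simulate a therapy-1 stimulation-parameter schedule
#'
#' Parameters are stepwise-constant within sub-periods of each programming
#' epoch, drawn over the evaluated ranges. Sub-period changes may be
#' programmed mid-hour; these are emitted as timestamped change events and
#' the hourly table carries the value in force at the start of each hour
#' (the imputation rule). A configurable fraction of hours is flagged
#' stimulation-disabled, and hourly therapy-triggering detection counts are
#' drawn with occasional zero-detection hours.
#'
#' @param config an `rns_sim_config` (uses `epoch_plan`,
#'   `p_stim_disabled_hour`, `detection_rate`, `p_no_detection`).
#' @param n_hours schedule length; each epoch must span at least 720 h.
#' @param seed integer seed.
#' @return data.frame with hour_index, epoch number, burst-1/burst-2
#'   parameter columns, `b2_active`, `stim_enabled` and
#'   `n_therapy_detections`; change events (data.frame with fractional
#'   `time_h`) attached as attribute `"change_events"`.
#' @export
simulate_stim_schedule <- function(config, n_hours, seed) {
  plan <- config$epoch_plan
  if (is.null(plan$n_epochs) || plan$n_epochs < 1)
    rns_stop("epoch_plan must define at least one epoch", "rns_config_error")
  n_ep <- plan$n_epochs
  ep_len <- floor(n_hours / n_ep)
  if (ep_len < 720)
    rns_stop("each programming epoch must span at least 720 hours",
             "rns_config_error")
  n_sub <- if (is.null(plan$n_subperiods)) 3L else plan$n_subperiods
  p_mid <- if (is.null(plan$p_midhour_change)) 0.5 else plan$p_midhour_change

  set.seed(seed)
  epoch <- rep(seq_len(n_ep), times = c(rep(ep_len, n_ep - 1),
                                        n_hours - ep_len * (n_ep - 1)))
  # change events: one per sub-period, the first of each epoch at its start
  ev <- list()
  for (e in seq_len(n_ep)) {
    e_start <- (e - 1) * ep_len + 1
    e_hours <- sum(epoch == e)
    sub_len <- floor(e_hours / n_sub)
    for (s in seq_len(n_sub)) {
      boundary <- e_start + (s - 1) * sub_len
      minute <- if (s > 1 && runif(1) < p_mid) sample(59, 1) else 0
      pars <- .draw_param_set()
      b2_active <- runif(1) < 0.7
      b2 <- pars
      if (b2_active && runif(1) < 0.3)
        b2["charge_density"] <- pars["charge_density"] * runif(1, 0.8, 1.25)
      ev[[length(ev) + 1]] <- data.frame(
        time_h = boundary + minute / 60, epoch = e,
        b1_charge_density_uC_cm2 = pars[["charge_density"]],
        b1_frequency_hz = pars[["frequency"]],
        b1_pulse_width_us = pars[["pulse_width"]],
        b1_burst_duration_ms = pars[["burst_duration"]],
        b2_charge_density_uC_cm2 = if (b2_active) b2[["charge_density"]] else 0,
        b2_frequency_hz = if (b2_active) b2[["frequency"]] else 0,
        b2_pulse_width_us = if (b2_active) b2[["pulse_width"]] else 0,
        b2_burst_duration_ms = if (b2_active) b2[["burst_duration"]] else 0,
        b2_active = b2_active)
    }
  }
  events <- do.call(rbind, ev)

  # start-of-hour imputation: hour h carries the last event at time <= h
  hours <- seq_len(n_hours)
  idx <- findInterval(hours + 1e-9, events$time_h)
  idx[idx == 0] <- 1
  sched <- events[idx, -(1:2)]
  rownames(sched) <- NULL
  stim_enabled <- runif(n_hours) >= config$p_stim_disabled_hour
  detections <- rpois(n_hours, config$detection_rate)
  detections[runif(n_hours) < config$p_no_detection] <- 0L
  if (config$p_stim_disabled_hour >= 1) {
    sched[] <- lapply(sched, function(x) if (is.numeric(x)) 0 * x else x)
  }
  out <- cbind(data.frame(hour_index = hours, epoch = epoch), sched,
               data.frame(stim_enabled = stim_enabled,
                          n_therapy_detections = as.integer(detections)))
  attr(out, "change_events") <- events
  out
}

#' Simulate a cohort of hourly telemetry tables with ground truth
#'
#' Generates one hourly-record table per patient (in the analysis CSV
#' schema) plus a retained ground-truth object: per-hour latent states, the
#' transition log-odds used, per-patient cycle phases and intercepts.
#' Per-patient random cycle-phase offsets, montage and lead-location labels
#' are drawn from the master seed, so identical configurations reproduce
#' identical cohorts.
#'
#' @param config an `rns_sim_config`.
#' @return List of class `rns_cohort`: `patients` (named list of
#'   data.frames), `ground_truth` (named list), `epochs` (epoch metadata
#'   data.frame) and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$hours_per_patient
  ids <- sprintf("P%03d", seq_len(config$n_patients))
  montages <- sample(c("monopolar_leadtolead", "bipolar"),
                     config$n_patients, replace = TRUE)
  locations <- sample(c("mesiotemporal", "neocortical"),
                      config$n_patients, replace = TRUE)
  phase_offsets <- matrix(runif(config$n_patients *
                                  length(config$cycle_periods), 0, 2 * pi),
                          nrow = config$n_patients)
  intercepts <- rnorm(config$n_patients, 0, config$patient_intercept_sd)
  op_seeds <- matrix(sample.int(.Machine$integer.max, 3 * config$n_patients),
                     nrow = config$n_patients)

  patients <- list()
  truth <- list()
  epochs <- list()
  for (p in seq_len(config$n_patients)) {
    pcfg <- config
    pcfg$cycle_phases <- (config$cycle_phases + phase_offsets[p, ]) %%
      (2 * pi)
    comp <- simulate_cycle_intensity(pcfg, n)
    sched <- simulate_stim_schedule(pcfg, n, seed = op_seeds[p, 1])
    avg <- average_therapy_bursts(
      sched[, c("b1_charge_density_uC_cm2", "b1_frequency_hz",
                "b1_pulse_width_us", "b1_burst_duration_ms")],
      sched[, c("b2_charge_density_uC_cm2", "b2_frequency_hz",
                "b2_pulse_width_us", "b2_burst_duration_ms")],
      sched$b2_active)
    zero <- sched$n_therapy_detections == 0 | !sched$stim_enabled
    avg[zero, ] <- 0
    cats <- categorize_stim_params(avg[[1]], avg[[2]], avg[[3]], avg[[4]])
    chain <- simulate_state_chain(pcfg, comp, cats, seed = op_seeds[p, 2],
                                  patient_intercept = intercepts[p])
    counts <- simulate_counts(chain$states, comp, pcfg,
                              seed = op_seeds[p, 3])
    epoch_id <- sprintf("%s_E%02d", ids[p], sched$epoch)
    # programming epochs do not interrupt recording: the whole simulated
    # stretch is one continuous segment
    rec <- data.frame(
      patient_id = ids[p],
      epoch_id = epoch_id,
      segment_id = sprintf("%s_S01", ids[p]),
      hour_index = sched$hour_index,
      iea_count = counts$iea_count,
      le_count = counts$le_count,
      n_therapy_detections = sched$n_therapy_detections,
      b1_charge_density_uC_cm2 = sched$b1_charge_density_uC_cm2,
      b1_frequency_hz = sched$b1_frequency_hz,
      b1_pulse_width_us = sched$b1_pulse_width_us,
      b1_burst_duration_ms = sched$b1_burst_duration_ms,
      b2_charge_density_uC_cm2 = sched$b2_charge_density_uC_cm2,
      b2_frequency_hz = sched$b2_frequency_hz,
      b2_pulse_width_us = sched$b2_pulse_width_us,
      b2_burst_duration_ms = sched$b2_burst_duration_ms,
      b2_active = sched$b2_active,
      stim_enabled = sched$stim_enabled,
      montage = montages[p],
      location = locations[p])
    patients[[ids[p]]] <- rec
    gt <- chain$ground_truth
    gt$cycle_phases <- pcfg$cycle_phases
    gt$change_events <- attr(sched, "change_events")
    truth[[ids[p]]] <- gt
    epochs[[p]] <- data.frame(
      patient_id = ids[p],
      epoch_id = unique(epoch_id),
      n_hours = as.vector(table(factor(epoch_id, levels = unique(epoch_id)))),
      detection_settings_constant = TRUE,
      le_correspondence = config$le_correspondence,
      montage = montages[p], location = locations[p])
  }
  structure(list(patients = patients, ground_truth = truth,
                 epochs = do.call(rbind, epochs), config = config),
            class = "rns_cohort")
}

#' Write a simulated cohort to disk
#'
#' One CSV per patient in the analysis schema, an `epochs.csv` metadata
#' table, and a `ground_truth.json` sidecar (latent states run-length
#' encoded, configured coefficients verbatim).
#'
#' @param cohort an `rns_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (pid in names(cohort$patients)) {
    f <- file.path(dir, paste0(pid, ".csv"))
    write.csv(cohort$patients[[pid]], f, row.names = FALSE)
    files <- c(files, f)
  }
  ef <- file.path(dir, "epochs.csv")
  write.csv(cohort$epochs, ef, row.names = FALSE)
  gt <- lapply(cohort$ground_truth, function(g) {
    r <- rle(g$latent_states)
    list(state_run_lengths = r$lengths, state_run_values = r$values,
         true_transition_logodds = g$true_transition_logodds,
         cycle_phases = g$cycle_phases)
  })
  jf <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, ef, jf))
}
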