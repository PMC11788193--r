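# Preprocessing of raw burst-level hourly records into analysis-ready
# series: burst averaging, start-of-hour imputation of parameter changes,
# zeroing of parameters for unstimulated hours, epoch inclusion filters,
# and per-patient segment concatenation.

.PARAM_COLS <- c("charge_density", "frequency", "pulse_width",
                 "burst_duration")

#' Average therapy-1 parameters across the two bursts
#'
#' When the second burst is active with nonzero charge density, the four
#' parameters (charge density, frequency, pulse width, burst duration) are
#' the arithmetic mean of the two bursts; when the second burst is disabled
#' or its charge density is zero, the first-burst values are used.
#'
#' @param burst1,burst2 data.frames (or named vectors) with the four
#'   parameter columns, all values >= 0.
#' @param burst2_active logical, one per row.
#' @return data.frame with columns `charge_density`, `frequency`,
#'   `pulse_width`, `burst_duration`.
#' @export
average_therapy_bursts <- function(burst1, burst2, burst2_active) {
  b1 <- as.data.frame(as.list(burst1))
  b2 <- as.data.frame(as.list(burst2))
  if (ncol(b1) != 4 || ncol(b2) != 4)
    rns_stop("burst parameter tables must have exactly four columns",
             "rns_dimension_error")
  names(b1) <- names(b2) <- .PARAM_COLS
  if (any(b1 < 0, na.rm = TRUE) || any(b2 < 0, na.rm = TRUE))
    rns_stop("stimulation parameters must be nonnegative",
             "rns_validation_error")
  use_b2 <- burst2_active & b2$charge_density > 0
  out <- b1
  out[use_b2, ] <- (b1[use_b2, ] + b2[use_b2, ]) / 2
  rownames(out) <- NULL
  out
}

#' Impute per-hour parameters from timestamped change events
#'
#' Parameter changes can be programmed at any time of day; each hourly bin
#' `[h, h+1)` carries the parameter values in force at the *start* of the
#' hour, so a change at minute m > 0 of hour h takes effect from hour h+1.
#'
#' @param change_events data.frame with a numeric `time_h` column (hours,
#'   fractional) and one column per parameter, sorted by time; the first
#'   event must be at or before the first hour of the grid.
#' @param hours integer hour grid (labels of the left-closed hourly bins).
#' @return data.frame with `hour_index` and the parameter columns of
#'   `change_events` evaluated at each hour start.
#' @export
impute_hourly_params <- function(change_events, hours) {
  stopifnot(is.data.frame(change_events), "time_h" %in% names(change_events))
  ev <- change_events[order(change_events$time_h), , drop = FALSE]
  out_of_grid <- ev$time_h > max(hours)
  if (any(out_of_grid)) {
    warning(sprintf("%d change event(s) after the hour grid ignored",
                    sum(out_of_grid)))
    ev <- ev[!out_of_grid, , drop = FALSE]
  }
  if (nrow(ev) == 0 || ev$time_h[1] > min(hours))
    rns_stop("no change event covers the start of the hour grid",
             "rns_validation_error")
  idx <- findInterval(hours + 1e-9, ev$time_h)
  vals <- ev[idx, setdiff(names(ev), "time_h"), drop = FALSE]
  rownames(vals) <- NULL
  cbind(data.frame(hour_index = hours), vals)
}

#' Zero stimulation parameters for unstimulated hours
#'
#' For hours during which no detections triggered a therapy or stimulation
#' was disabled, the averaged charge density, frequency, pulse width and
#' burst duration are set to zero. Counts are never altered.
#'
#' @param records data.frame with columns `n_therapy_detections`,
#'   `stim_enabled` and the four averaged parameter columns
#'   (`charge_density`, `frequency`, `pulse_width`, `burst_duration`).
#' @return `records` with parameters zeroed where the rule applies.
#' @export
apply_zeroing_rule <- function(records) {
  stopifnot(all(c("n_therapy_detections", "stim_enabled",
                  .PARAM_COLS) %in% names(records)))
  zero <- records$n_therapy_detections == 0 | !records$stim_enabled
  records[zero, .PARAM_COLS] <- 0
  records
}

#' Filter programming epochs for inclusion
#'
#' Retains epochs with constant detection settings, at least `min_days`
#' days of data, and a fraction of long episodes corresponding to
#' electrographic seizures strictly greater than `min_correspondence`
#' (an externally supplied annotation from visual review; never computed
#' here). Exclusion reasons are reported per epoch.
#'
#' @param epochs data.frame with columns `epoch_id`, `n_hours`,
#'   `detection_settings_constant`, `le_correspondence`.
#' @param min_days minimum epoch length in days (default 30; epochs of
#'   exactly `24 * min_days` hours are included).
#' @param min_correspondence strict lower bound on `le_correspondence`
#'   (default 0.90).
#' @return List with `included` (subset of `epochs`) and `exclusions`
#'   (data.frame of `epoch_id`, `reason`).
#' @export
apply_epoch_filters <- function(epochs, min_days = 30,
                                min_correspondence = 0.90) {
  stopifnot(all(c("epoch_id", "n_hours", "detection_settings_constant",
                  "le_correspondence") %in% names(epochs)))
  reason <- rep(NA_character_, nrow(epochs))
  unann <- is.na(epochs$le_correspondence)
  reason[unann] <- "unannotated"
  ok <- !unann
  bad_set <- ok & !epochs$detection_settings_constant
  reason[bad_set] <- "detection_settings_changed"
  short <- ok & !bad_set & epochs$n_hours < 24 * min_days
  reason[short] <- sprintf("shorter_than_%d_days", min_days)
  lowc <- ok & !bad_set & !short &
    epochs$le_correspondence <= min_correspondence
  reason[lowc] <- "le_correspondence_too_low"
  keep <- is.na(reason)
  list(included = epochs[keep, , drop = FALSE],
       exclusions = data.frame(epoch_id = epochs$epoch_id[!keep],
                               reason = reason[!keep]))
}

#' Concatenate continuous segments within each patient
#'
#' Orders records by hour index within patient, preserving segment
#' identifiers so that downstream stages never form a transition across a
#' segment boundary.
#'
#' @param records data.frame with `patient_id`, `segment_id`, `hour_index`.
#' @return `records`, ordered by patient then hour index.
#' @export
concatenate_segments <- function(records) {
  stopifnot(all(c("patient_id", "segment_id", "hour_index") %in%
                  names(records)))
  dup <- stats::ave(records$hour_index,
                    records$patient_id,
                    FUN = function(x) duplicated(x))
  if (any(dup > 0))
    rns_stop("duplicate hour_index within patient", "rns_validation_error")
  records[order(records$patient_id, records$hour_index), , drop = FALSE]
}
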