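# Categorization of averaged therapy-1 stimulation parameters into the
# evaluated ranges, relative to the manufacturer-recommended initial
# settings (charge density <= 0.5 uC/cm2, frequency 200 Hz, pulse width
# 160 us, burst duration 100 ms). Interval brackets are honoured as
# printed: "(3, 4]" is left-open right-closed, "(20, 100)" is open.

.EQ_TOL <- 1e-8

#' Category levels for averaged stimulation parameters
#'
#' Reference level first; used to build factors with the baseline device
#' settings as the reference category in transition models.
#'
#' @return Named list of character vectors (`charge_density`, `frequency`,
#'   `pulse_width`, `burst_duration`).
#' @export
stim_category_levels <- function() {
  list(
    charge_density = c("cd_le0.5", "cd_0.5_3", "cd_3_4", "cd_4_5",
                       "cd_5_6", "cd_6_7", "cd_gt7"),
    frequency = c("fq_200", "fq_le20", "fq_20_100", "fq_100",
                  "fq_100_200", "fq_gt200"),
    pulse_width = c("pw_160", "pw_lt160", "pw_gt160"),
    burst_duration = c("bd_100", "bd_lt100", "bd_100_500", "bd_gt500")
  )
}

.cat_charge_density <- function(x) {
  ifelse(x <= 0.5 + .EQ_TOL, "cd_le0.5",
  ifelse(x <= 3 + .EQ_TOL, "cd_0.5_3",
  ifelse(x <= 4 + .EQ_TOL, "cd_3_4",
  ifelse(x <= 5 + .EQ_TOL, "cd_4_5",
  ifelse(x <= 6 + .EQ_TOL, "cd_5_6",
  ifelse(x <= 7 + .EQ_TOL, "cd_6_7", "cd_gt7"))))))
}

.cat_frequency <- function(x) {
  ifelse(abs(x - 200) <= .EQ_TOL, "fq_200",
  ifelse(x <= 20 + .EQ_TOL, "fq_le20",
  ifelse(x < 100 - .EQ_TOL, "fq_20_100",
  ifelse(abs(x - 100) <= .EQ_TOL, "fq_100",
  ifelse(x < 200, "fq_100_200", "fq_gt200")))))
}

.cat_pulse_width <- function(x) {
  ifelse(abs(x - 160) <= .EQ_TOL, "pw_160",
         ifelse(x < 160, "pw_lt160", "pw_gt160"))
}

.cat_burst_duration <- function(x) {
  ifelse(abs(x - 100) <= .EQ_TOL, "bd_100",
  ifelse(x < 100, "bd_lt100",
  ifelse(x <= 500 + .EQ_TOL, "bd_100_500", "bd_gt500")))
}

#' Categorize averaged therapy-1 stimulation parameters
#'
#' Maps each hour's averaged charge density, stimulation frequency, pulse
#' width and burst duration to the evaluated parameter ranges. Hours with
#' all four parameters zero (the zeroing rule: no detections, no stimulated
#' episodes, or stimulation disabled) map to every reference category, so
#' the model intercept reflects the baseline transition rate in the absence
#' of stimulation.
#'
#' @param charge_density averaged charge density, uC/cm2 (>= 0).
#' @param frequency averaged stimulation frequency, Hz (>= 0).
#' @param pulse_width averaged pulse width, us (>= 0).
#' @param burst_duration averaged burst duration, ms (>= 0).
#' @return A data.frame of four factor columns (`charge_density_cat`,
#'   `frequency_cat`, `pulse_width_cat`, `burst_duration_cat`) whose levels
#'   are given by [stim_category_levels()], reference level first.
#' @examples
#' categorize_stim_params(3.5, 90, 160, 2000)
#' @export
categorize_stim_params <- function(charge_density, frequency,
                                   pulse_width, burst_duration) {
  n <- length(charge_density)
  stopifnot(length(frequency) == n, length(pulse_width) == n,
            length(burst_duration) == n)
  if (any(charge_density < 0 | frequency < 0 |
          pulse_width < 0 | burst_duration < 0, na.rm = TRUE))
    rns_stop("stimulation parameters must be nonnegative", "rns_config_error")
  lv <- stim_category_levels()
  no_stim <- charge_density == 0 & frequency == 0 &
    pulse_width == 0 & burst_duration == 0
  cd <- .cat_charge_density(charge_density)
  fq <- .cat_frequency(frequency)
  pw <- .cat_pulse_width(pulse_width)
  bd <- .cat_burst_duration(burst_duration)
  cd[no_stim] <- lv$charge_density[1]
  fq[no_stim] <- lv$frequency[1]
  pw[no_stim] <- lv$pulse_width[1]
  bd[no_stim] <- lv$burst_duration[1]
  data.frame(
    charge_density_cat = factor(cd, levels = lv$charge_density),
    frequency_cat = factor(fq, levels = lv$frequency),
    pulse_width_cat = factor(pw, levels = lv$pulse_width),
    burst_duration_cat = factor(bd, levels = lv$burst_duration)
  )
}

# All non-reference category codes, used to validate configured ground-truth
# stimulation effects in the synthetic-cohort generator.
.nonref_categories <- function() {
  unlist(lapply(stim_category_levels(), function(x) x[-1]), use.names = FALSE)
}
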