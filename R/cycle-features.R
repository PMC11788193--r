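# Cycle-phase features: z-scored IEA counts are band-pass filtered into
# circadian and multidien bands (0.8-1.2 x the nominal period) with a
# first-order Butterworth filter applied forward then backward (zero phase
# lag, since phase is interpreted downstream), instantaneous phase is taken
# from the Hilbert analytic signal and shifted by pi so that the rising
# half of each cycle occupies (0, pi), and the five shifted phases plus
# log-transformed LE counts form the feature matrix reduced by PCA.

#' Band specification for cycle filtering
#'
#' Passband edges at 0.8 and 1.2 times the nominal period, e.g. the
#' circadian band spans 19.2--28.8 h.
#'
#' @param nominal_period nominal cycle period in hours.
#' @return List of class `rns_band` with `nominal_period`, `low_edge`,
#'   `high_edge` (hours).
#' @export
band_spec <- function(nominal_period) {
  stopifnot(nominal_period > 0)
  structure(list(nominal_period = nominal_period,
                 low_edge = 0.8 * nominal_period,
                 high_edge = 1.2 * nominal_period),
            class = "rns_band")
}

#' Default circadian and multidien bands
#'
#' The circadian band plus multidien bands at 7, 15, 20 and 30 days,
#' the periodicities prevalent in interictal epileptiform activity.
#'
#' @param periods nominal periods in hours.
#' @return List of [band_spec()] objects.
#' @export
default_bands <- function(periods = c(24, 168, 360, 480, 720)) {
  lapply(periods, band_spec)
}

#' Z-transform a series
#'
#' Centres to mean 0 and scales to sample standard deviation 1. A constant
#' series is returned as zeros with a warning (standard-deviation floor).
#'
#' @param series numeric vector, length >= 2.
#' @return Standardized numeric vector.
#' @export
zscore_series <- function(series) {
  stopifnot(length(series) >= 2)
  s <- sd(series)
  if (!is.finite(s) || s == 0) {
    warning("constant series: z-scores set to zero")
    return(rep(0, length(series)))
  }
  (series - mean(series)) / s
}

#' Zero-phase first-order Butterworth band-pass filter
#'
#' Cutoff frequencies at `1/high_edge` and `1/low_edge` cycles/hour.
#' The filter is applied forward then backward, so the net response has
#' zero phase lag (the squared magnitude of the one-pass filter). The
#' series is reflect-padded by `min(3 * high_edge, length - 1)` samples
#' before filtering to suppress edge transients on epoch-length series.
#'
#' @param series numeric vector (hourly samples).
#' @param band an `rns_band`.
#' @param fs sampling rate in samples/hour (default 1).
#' @return Filtered series, same length as the input.
#' @export
bandpass_filter <- function(series, band, fs = 1) {
  if (band$low_edge <= 2 / fs)
    rns_stop("band edge period at or below the Nyquist limit (2 samples)",
             "rns_config_error")
  n <- length(series)
  if (n < 4 * band$high_edge * fs)
    warning(sprintf(
      "series (%d samples) shorter than 4 periods of the %g-h band",
      n, band$nominal_period))
  W <- c(1 / band$high_edge, 1 / band$low_edge) / (fs / 2)
  bf <- signal::butter(1, W, type = "pass")
  # remove the mean up front: DC is outside every passband, and demeaning
  # kills the slowly decaying step transient a constant offset would excite
  series <- series - mean(series)
  npad <- min(ceiling(3 * band$high_edge * fs), n - 1)
  front <- series[(npad + 1):2]
  back <- series[(n - 1):(n - npad)]
  x <- c(front, series, back)
  y <- signal::filter(bf, x)
  y <- rev(signal::filter(bf, rev(y)))
  y[(npad + 1):(npad + n)]
}

# Analytic signal via the frequency-domain Hilbert transform.
.analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous shifted phase of a band-limited series
#'
#' Raw analytic-signal phase phi in `[-pi, pi)` is mapped to
#' `(phi + pi) mod 2*pi`, so the rising half of the oscillation occupies
#' `(0, pi)` (peaking at pi, the cycle peak) and the falling half
#' `(pi, 2*pi)`: higher shifted-phase values within the rising half
#' correspond to the peak of the upgoing phase.
#'
#' @param filtered band-pass-filtered, zero-mean numeric vector.
#' @return Phase per sample, radians in `[0, 2*pi)`.
#' @export
instantaneous_shifted_phase <- function(filtered) {
  if (all(filtered == 0)) {
    warning("all-zero input: phase undefined, returning 0")
    return(rep(0, length(filtered)))
  }
  phi <- Arg(.analytic_signal(filtered))
  (phi + pi) %% (2 * pi)
}

#' Assemble the cycle-phase feature matrix
#'
#' Five shifted band phases plus `log(1 + LE count)` per hour.
#'
#' @param shifted_phases matrix or data.frame, one column per band, values
#'   in `[0, 2*pi)`.
#' @param le_counts nonnegative integer vector, aligned to the phase rows.
#' @return Numeric matrix with the phase columns and a `log_le` column.
#' @export
assemble_feature_matrix <- function(shifted_phases, le_counts) {
  ph <- as.matrix(shifted_phases)
  if (nrow(ph) != length(le_counts))
    rns_stop("phases and LE counts must cover the same hours",
             "rns_dimension_error")
  cbind(ph, log_le = log1p(le_counts))
}

#' Principal components of the feature matrix
#'
#' Columns are centred and scaled to unit variance, then decomposed by PCA.
#' Returns the first `n_components` score columns, all explained-variance
#' fractions, the loadings, and the smallest number of components whose
#' cumulative explained variance reaches `variance_target` (diagnostic for
#' the choose-enough-components rule).
#'
#' @param features numeric matrix (>= `ncol + 1` rows).
#' @param n_components number of score columns to keep (default 5).
#' @param variance_target cumulative explained-variance target
#'   (default 0.80).
#' @return List of class `rns_cycle_features` with `scores`,
#'   `explained_variance`, `loadings`, `k_variance`, `center`, `scale`.
#' @export
reduce_pca <- function(features, n_components = 5, variance_target = 0.80) {
  features <- as.matrix(features)
  if (n_components > ncol(features))
    rns_stop("n_components exceeds the number of feature columns",
             "rns_config_error")
  if (nrow(features) <= ncol(features))
    rns_stop("need more feature rows than columns for PCA",
             "rns_config_error")
  sds <- apply(features, 2, sd)
  sds[sds == 0] <- 1
  std <- scale(features, center = TRUE, scale = sds)
  pc <- prcomp(std, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 explained_variance = ev,
                 loadings = pc$rotation,
                 k_variance = which(cumsum(ev) >= variance_target)[1],
                 center = attr(std, "scaled:center"),
                 scale = sds),
            class = "rns_cycle_features")
}

#' Per-segment cycle features for one patient
#'
#' For each contiguous segment: z-scores the IEA counts, filters each band,
#' extracts shifted phases, and assembles the phase + log-LE feature rows;
#' rows are then concatenated across segments (the Hilbert transform is
#' never taken across a recording gap) and reduced by patient-level PCA.
#'
#' @param records one patient's hourly records (`segment_id`, `hour_index`,
#'   `iea_count`, `le_count`), ordered by hour.
#' @param bands list of [band_spec()] (default [default_bands()]).
#' @param n_components,variance_target passed to [reduce_pca()].
#' @return List with `features` (raw 6-column matrix), `pca`
#'   (`rns_cycle_features`), `shifted_phases`, `hours`, `segments`.
#' @export
patient_cycle_features <- function(records, bands = default_bands(),
                                   n_components = 5,
                                   variance_target = 0.80) {
  seg_ids <- unique(records$segment_id)
  phase_list <- vector("list", length(seg_ids))
  for (i in seq_along(seg_ids)) {
    seg <- records[records$segment_id == seg_ids[i], ]
    z <- zscore_series(seg$iea_count)
    ph <- vapply(bands, function(b)
      instantaneous_shifted_phase(bandpass_filter(z, b)),
      numeric(nrow(seg)))
    colnames(ph) <- paste0("phase_", vapply(bands, `[[`, 0,
                                            "nominal_period"))
    phase_list[[i]] <- ph
  }
  phases <- do.call(rbind, phase_list)
  feats <- assemble_feature_matrix(phases, records$le_count)
  list(features = feats,
       pca = reduce_pca(feats, n_components, variance_target),
       shifted_phases = phases,
       hours = records$hour_index,
       segments = records$segment_id)
}
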