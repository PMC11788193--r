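# State-dependent transition modelling: one transition row per eligible
# patient-hour (response: next-hour state is low risk), stratified by
# (lead location, stimulation montage, current state), fit by mixed-effects
# logistic regression (patient random intercept plus patient random slope
# on scaled days since implant) or plain logistic regression for
# low-sample strata, with Holm-adjusted Wald inference and Nakagawa
# marginal/conditional R-squared.

#' Build the transition design from decoded states and hourly records
#'
#' For each hour t whose successor t+1 lies in the same segment, emits one
#' row: response `1{state(t+1) = low}`, covariates from hour t (parameter
#' categories, averaged continuous parameter values, therapy-triggering
#' detections, days since implant), stratum from the current state plus the
#' patient's lead location and montage. The last hour of each segment emits
#' no row, so no transition spans a recording gap.
#'
#' @param states integer decoded states (1 = low, 2 = high), one per row of
#'   `records` (same order).
#' @param records hourly records with `patient_id`, `segment_id`,
#'   `hour_index`, `n_therapy_detections`, `montage`, `location`, and the
#'   averaged (post-zeroing) parameter columns `charge_density`,
#'   `frequency`, `pulse_width`, `burst_duration`.
#' @param categories data.frame from [categorize_stim_params()], one row
#'   per record row.
#' @return data.frame of class `rns_transition_design` with `response`,
#'   `current_state`, the category factors, scaled-ready continuous
#'   covariates (`n_detections`, `days_since_implant`, and the raw
#'   parameter values), `patient_id` and `stratum`.
#' @export
build_transition_design <- function(states, records, categories) {
  stopifnot(length(states) == nrow(records),
            nrow(categories) == nrow(records))
  key <- paste(records$patient_id, records$segment_id)
  n <- nrow(records)
  nxt <- c(key[-1] == key[-n] &
             records$hour_index[-1] == records$hour_index[-n] + 1, FALSE)
  idx <- which(nxt)
  if (!length(idx))
    return(structure(data.frame(), class = c("rns_transition_design",
                                             "data.frame")))
  out <- data.frame(
    patient_id = records$patient_id[idx],
    response = as.integer(states[idx + 1] == 1L),
    current_state = factor(ifelse(states[idx] == 1L, "low", "high"),
                           levels = c("low", "high")),
    categories[idx, , drop = FALSE],
    charge_density = records$charge_density[idx],
    frequency = records$frequency[idx],
    pulse_width = records$pulse_width[idx],
    burst_duration = records$burst_duration[idx],
    n_detections = records$n_therapy_detections[idx],
    days_since_implant = records$hour_index[idx] / 24,
    montage = records$montage[idx],
    location = records$location[idx])
  out$stratum <- interaction(out$location, out$montage, out$current_state,
                             sep = ":", drop = TRUE)
  rownames(out) <- NULL
  structure(out, class = c("rns_transition_design", "data.frame"))
}

# Centre and scale a covariate; constant columns are returned as zeros.
.cscale <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Model frame for one stratum: response, scaled continuous covariates,
# and either category factors (dropping levels with no rows, which are
# reported as untrialled) or scaled continuous parameter values.
.stratum_frame <- function(design, covariate_mode) {
  df <- as.data.frame(design)
  df$n_detections_s <- .cscale(df$n_detections)
  df$days_s <- .cscale(df$days_since_implant)
  terms <- c("n_detections_s", "days_s")[
    c(sd(df$n_detections_s) > 0, sd(df$days_s) > 0)]
  untrialled <- character(0)
  if (covariate_mode == "categorical") {
    for (col in c("charge_density_cat", "frequency_cat", "pulse_width_cat",
                  "burst_duration_cat")) {
      lv <- levels(df[[col]])
      present <- lv[lv %in% unique(as.character(df[[col]]))]
      untrialled <- c(untrialled,
                      paste0(col, setdiff(lv[-1], present)))
      df[[col]] <- factor(as.character(df[[col]]),
                          levels = c(lv[1], setdiff(present, lv[1])))
      if (nlevels(df[[col]]) > 1) terms <- c(terms, col)
    }
  } else {
    for (col in c("charge_density", "frequency", "pulse_width",
                  "burst_duration")) {
      sc <- paste0(col, "_s")
      df[[sc]] <- .cscale(df[[col]])
      if (sd(df[[sc]]) > 0) terms <- c(terms, sc)
    }
  }
  list(df = df, terms = terms, untrialled = untrialled)
}

# Detect quasi-complete separation: a covariate level whose rows all share
# one response value.
.separation_flags <- function(df, terms) {
  flags <- character(0)
  for (tm in terms) {
    x <- df[[tm]]
    if (!is.factor(x)) next
    for (lv in levels(x)[-1]) {
      y <- df$response[x == lv]
      if (length(y) > 0 && length(unique(y)) == 1)
        flags <- c(flags, paste0(tm, lv))
    }
  }
  flags
}

.wald_table <- function(est, se, holm_family) {
  z <- est / se
  p_raw <- 2 * pnorm(-abs(z))
  p_holm <- rep(NA_real_, length(est))
  fam <- names(est) %in% holm_family
  p_holm[fam] <- holm_adjust(p_raw[fam])
  data.frame(term = names(est), estimate = est, se = se,
             odds_ratio = exp(est),
             ci_low = exp(est - qnorm(0.975) * se),
             ci_high = exp(est + qnorm(0.975) * se),
             p_raw = p_raw, p_holm = p_holm,
             significant = !is.na(p_holm) & p_holm < 0.05,
             row.names = NULL)
}

.finish_fit <- function(tab, sigma2_fixed, sigma2_random, re_variances,
                        aic, n_rows, n_patients, mode, covariate_mode,
                        stratum, untrialled, separation, converged = TRUE) {
  r2 <- r2_glmm(sigma2_fixed, sigma2_random)
  structure(list(stratum = stratum, coefficients = tab,
                 random_effect_variances = re_variances,
                 r2_marginal = r2[["r2_marginal"]],
                 r2_conditional = r2[["r2_conditional"]],
                 aic = aic, n_rows = n_rows, n_patients = n_patients,
                 mode = mode, covariate_mode = covariate_mode,
                 untrialled = untrialled, separation_flags = separation,
                 converged = converged),
            class = "transition_fit")
}

#' Mixed-effects logistic transition model for one stratum
#'
#' Logistic regression of next-hour low-state probability on the stimulation
#' covariates with a per-patient random intercept and an independent
#' per-patient random slope on scaled days since implant, fit by Laplace
#' approximation. Wald 95% CIs on the log-odds scale are exponentiated for
#' reporting; Holm adjustment spans all non-intercept fixed terms of the
#' fit.
#'
#' @param design rows of an `rns_transition_design` belonging to one
#'   stratum (>= 2 patients, >= 200 rows).
#' @param covariate_mode `"categorical"` (parameter-range indicators) or
#'   `"continuous"` (centred/scaled parameter values).
#' @return Object of class `transition_fit`.
#' @export
fit_mixed_logistic <- function(design,
                               covariate_mode = c("categorical",
                                                  "continuous")) {
  covariate_mode <- match.arg(covariate_mode)
  if (length(unique(design$patient_id)) < 2 || nrow(design) < 200)
    rns_stop("mixed mode needs >= 2 patients and >= 200 rows",
             "rns_config_error")
  sf <- .stratum_frame(design, covariate_mode)
  df <- sf$df
  if (length(unique(df$response)) < 2)
    rns_stop("response is constant in this stratum (complete separation)",
             "rns_separation_error")
  sep <- .separation_flags(df, sf$terms)
  if (length(sep))
    warning(paste("possible quasi-complete separation:",
                  paste(sep, collapse = ", ")))
  fe <- if (length(sf$terms)) paste(sf$terms, collapse = " + ") else "1"
  re <- if ("days_s" %in% sf$terms)
    "(1 | patient_id) + (0 + days_s | patient_id)" else "(1 | patient_id)"
  fml <- as.formula(paste("response ~", fe, "+", re))
  fit <- lme4::glmer(fml, data = df, family = binomial(),
                     control = lme4::glmerControl(
                       calc.derivs = FALSE,
                       check.conv.singular = "ignore"))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  tab <- .wald_table(est, se, holm_family = setdiff(names(est),
                                                    "(Intercept)"))
  Xb <- as.vector(model.matrix(fit) %*% est)
  vc <- lme4::VarCorr(fit)
  re_var <- vapply(vc, function(m) sum(diag(m)), 0)
  .finish_fit(tab, var(Xb), sum(re_var), re_var,
              aic = stats::AIC(fit), n_rows = nrow(df),
              n_patients = length(unique(df$patient_id)),
              mode = "mixed", covariate_mode = covariate_mode,
              stratum = as.character(design$stratum[1]),
              untrialled = sf$untrialled, separation = sep)
}

#' Fixed-effects logistic transition model for one stratum
#'
#' Plain logistic regression for strata with too few patients to estimate
#' random effects (e.g. bipolar neocortical stimulation). In continuous
#' mode the stimulation parameters enter as centred and scaled values
#' rather than range indicators.
#'
#' @inheritParams fit_mixed_logistic
#' @return Object of class `transition_fit` with `mode = "fixed_only"`.
#' @export
fit_fixed_logistic <- function(design,
                               covariate_mode = c("categorical",
                                                  "continuous")) {
  covariate_mode <- match.arg(covariate_mode)
  if (nrow(design) < 50)
    rns_stop("fixed mode needs >= 50 rows", "rns_config_error")
  sf <- .stratum_frame(design, covariate_mode)
  df <- sf$df
  if (length(unique(df$response)) < 2)
    rns_stop("response is constant in this stratum (complete separation)",
             "rns_separation_error")
  sep <- .separation_flags(df, sf$terms)
  if (length(sep))
    warning(paste("possible quasi-complete separation:",
                  paste(sep, collapse = ", ")))
  fe <- if (length(sf$terms)) paste(sf$terms, collapse = " + ") else "1"
  fml <- as.formula(paste("response ~", fe))
  fit <- glm(fml, data = df, family = binomial())
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  tab <- .wald_table(est, se, holm_family = setdiff(names(est),
                                                    "(Intercept)"))
  Xb <- as.vector(model.matrix(fit) %*% est)
  .finish_fit(tab, var(Xb), 0, numeric(0),
              aic = stats::AIC(fit), n_rows = nrow(df),
              n_patients = length(unique(df$patient_id)),
              mode = "fixed_only", covariate_mode = covariate_mode,
              stratum = as.character(design$stratum[1]),
              untrialled = sf$untrialled, separation = sep)
}

#' Holm step-down adjustment
#'
#' Family-wise error rate control across the non-intercept fixed terms of
#' one fit: sort ascending, multiply the i-th smallest by (m - i + 1),
#' enforce a monotone cumulative maximum, cap at 1.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "holm")
}

#' Marginal and conditional R-squared for a logistic mixed model
#'
#' Nakagawa-style decomposition for the logit link:
#' `r2_marginal = s2_fixed / (s2_fixed + s2_random + pi^2 / 3)` and
#' `r2_conditional = (s2_fixed + s2_random) / (same denominator)`, where
#' `s2_fixed` is the sample variance of the fixed-effect linear predictor
#' and `s2_random` the summed random-effect variances (zero in fixed-only
#' fits, making the two coincide).
#'
#' @param sigma2_fixed variance of the fixed-effect linear predictor.
#' @param sigma2_random sum of random-effect variances.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_glmm <- function(sigma2_fixed, sigma2_random = 0) {
  denom <- sigma2_fixed + sigma2_random + pi^2 / 3
  c(r2_marginal = sigma2_fixed / denom,
    r2_conditional = (sigma2_fixed + sigma2_random) / denom)
}

#' Summarize per-stratum transition fits
#'
#' Tidy table across strata: exponentiated estimates with 95% CIs,
#' Holm-adjusted p-values, significance flags at 0.05, R-squared values,
#' AIC and row counts, with explicit markers for untrialled parameter
#' ranges and strata that could not be estimated.
#'
#' @param fits list of `transition_fit` objects (or, for strata that could
#'   not be estimated, a list with `stratum` and `reason`).
#' @return data.frame, one row per term per stratum.
#' @export
summarize_stratum_fits <- function(fits) {
  if (!length(fits)) return(data.frame())
  rows <- lapply(fits, function(f) {
    if (!inherits(f, "transition_fit")) {
      return(data.frame(stratum = f$stratum, term = "(not estimated)",
                        estimate = NA, se = NA, odds_ratio = NA,
                        ci_low = NA, ci_high = NA, p_raw = NA, p_holm = NA,
                        significant = NA, note = f$reason,
                        r2_marginal = NA, r2_conditional = NA, aic = NA,
                        n_rows = NA))
    }
    tab <- f$coefficients
    tab$note <- ""
    if (length(f$untrialled))
      tab <- rbind(tab, data.frame(term = f$untrialled, estimate = NA,
                                   se = NA, odds_ratio = NA, ci_low = NA,
                                   ci_high = NA, p_raw = NA, p_holm = NA,
                                   significant = NA, note = "Not trialed"))
    tab$stratum <- f$stratum
    tab$r2_marginal <- f$r2_marginal
    tab$r2_conditional <- f$r2_conditional
    tab$aic <- f$aic
    tab$n_rows <- f$n_rows
    tab[, c("stratum", "term", "estimate", "se", "odds_ratio", "ci_low",
            "ci_high", "p_raw", "p_holm", "significant", "note",
            "r2_marginal", "r2_conditional", "aic", "n_rows")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
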