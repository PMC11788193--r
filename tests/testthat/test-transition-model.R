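test_that("parameter categorization matches the evaluated ranges", {
  c1 <- categorize_stim_params(3.5, 90, 160, 2000)
  expect_equal(as.character(c1$charge_density_cat), "cd_3_4")
  expect_equal(as.character(c1$frequency_cat), "fq_20_100")
  expect_equal(as.character(c1$burst_duration_cat), "bd_gt500")

  # manufacturer-recommended initial settings map to every reference level
  base <- categorize_stim_params(0.5, 200, 160, 100)
  expect_equal(as.character(unlist(base)),
               c("cd_le0.5", "fq_200", "pw_160", "bd_100"))

  # interval boundaries as printed: (0.5, 3], (3, 4], exact 100/200 Hz
  cd <- categorize_stim_params(c(0.5, 0.51, 3, 3.01, 7, 7.1),
                               rep(200, 6), rep(160, 6), rep(100, 6))
  expect_equal(as.character(cd$charge_density_cat),
               c("cd_le0.5", "cd_0.5_3", "cd_0.5_3", "cd_3_4", "cd_6_7",
                 "cd_gt7"))
  fq <- categorize_stim_params(rep(0.5, 6), c(20, 20.5, 100, 150, 200,
                                              266.65),
                               rep(160, 6), rep(100, 6))
  expect_equal(as.character(fq$frequency_cat),
               c("fq_le20", "fq_20_100", "fq_100", "fq_100_200", "fq_200",
                 "fq_gt200"))
  pw <- categorize_stim_params(rep(0.5, 3), rep(200, 3), c(80, 160, 240),
                               rep(100, 3))
  expect_equal(as.character(pw$pulse_width_cat),
               c("pw_lt160", "pw_160", "pw_gt160"))
  bd <- categorize_stim_params(rep(0.5, 4), rep(200, 4), rep(160, 4),
                               c(50, 100, 500, 501))
  expect_equal(as.character(bd$burst_duration_cat),
               c("bd_lt100", "bd_100", "bd_100_500", "bd_gt500"))

  # zeroed (unstimulated) hours map to every reference level
  z <- categorize_stim_params(0, 0, 0, 0)
  expect_equal(as.character(unlist(z)),
               c("cd_le0.5", "fq_200", "pw_160", "bd_100"))
  expect_error(categorize_stim_params(-1, 200, 160, 100),
               class = "rns_config_error")
})

test_that("transition design emits one row per within-segment hour pair", {
  rec <- make_records(3)
  cats <- categorize_stim_params(rec$charge_density, rec$frequency,
                                 rec$pulse_width, rec$burst_duration)
  des <- build_transition_design(c(1L, 2L, 1L), rec, cats)
  expect_equal(nrow(des), 2)
  expect_equal(as.character(des$current_state), c("low", "high"))
  expect_equal(des$response, c(0L, 1L))

  # no row spans a segment boundary
  rec2 <- rbind(make_records(3, segment_id = "S1"),
                make_records(3, segment_id = "S2", hour_start = 100))
  cats2 <- categorize_stim_params(rec2$charge_density, rec2$frequency,
                                  rec2$pulse_width, rec2$burst_duration)
  des2 <- build_transition_design(rep(1L, 6), rec2, cats2)
  expect_equal(nrow(des2), 4)
  expect_false(any(des2$days_since_implant == 3 / 24))

  # all low-state hours: the high stratum is empty
  expect_equal(sum(des2$current_state == "high"), 0)

  # a single-hour segment contributes no rows
  des3 <- build_transition_design(1L, make_records(1), cats[1, ])
  expect_equal(nrow(des3), 0)
})

test_that("fixed logistic fit equals closed-form 2x2 log odds ratio", {
  set.seed(17)
  n <- 4000
  bd <- sample(c(100, 2000), n, replace = TRUE)
  p <- plogis(-1 + 0.8 * (bd > 500))
  y <- rbinom(n, 1, p)
  rec <- make_records(n, detections = 5, bd = bd)
  cats <- categorize_stim_params(rec$charge_density, rec$frequency,
                                 rec$pulse_width, rec$burst_duration)
  des <- build_transition_design(c(1L, rep(1L, n - 1)), rec, cats)
  # overwrite response with the synthetic Bernoulli draw for hours 1..n-1
  des$response <- y[-n]
  des$days_since_implant <- 0   # collapse to the single binary covariate
  fit <- fit_fixed_logistic(des)
  b <- fit$coefficients
  est <- b$estimate[b$term == "burst_duration_catbd_gt500"]
  expect_equal(est, logodds_2x2(as.numeric(bd[-n] > 500), y[-n]),
               tolerance = 1e-6)
})

test_that("intercept-only fixed fit recovers the sample log odds", {
  set.seed(3)
  n <- 500
  rec <- make_records(n)
  cats <- categorize_stim_params(rec$charge_density, rec$frequency,
                                 rec$pulse_width, rec$burst_duration)
  des <- build_transition_design(rep(1L, n), rec, cats)
  des$response <- rbinom(n - 1, 1, 0.37)
  des$days_since_implant <- 0
  fit <- fit_fixed_logistic(des)
  expect_equal(fit$coefficients$estimate[1],
               qlogis(mean(des$response)), tolerance = 1e-6)
  expect_equal(fit$r2_marginal, fit$r2_conditional)
})

test_that("constant response triggers the separation error path", {
  rec <- make_records(300)
  cats <- categorize_stim_params(rec$charge_density, rec$frequency,
                                 rec$pulse_width, rec$burst_duration)
  des <- build_transition_design(rep(1L, 300), rec, cats)
  des$response <- 0L
  expect_error(fit_fixed_logistic(des), class = "rns_separation_error")
})

test_that("mixed fit reduces to the fixed fit when variance is absent", {
  set.seed(23)
  n_pat <- 6; n_h <- 400
  recs <- do.call(rbind, lapply(seq_len(n_pat), function(p) {
    bd <- sample(c(100, 300, 2000), n_h, replace = TRUE)
    make_records(n_h, patient_id = sprintf("P%d", p),
                 segment_id = sprintf("P%d_S", p), bd = bd)
  }))
  cats <- categorize_stim_params(recs$charge_density, recs$frequency,
                                 recs$pulse_width, recs$burst_duration)
  des <- build_transition_design(rep(1L, nrow(recs)), recs, cats)
  eta <- -0.5 + 0.6 * (des$burst_duration_cat == "bd_gt500")
  des$response <- rbinom(nrow(des), 1, plogis(eta))
  fx <- fit_fixed_logistic(des)
  mx <- suppressWarnings(suppressMessages(fit_mixed_logistic(des)))
  fterm <- fx$coefficients
  mterm <- mx$coefficients
  shared <- intersect(fterm$term, mterm$term)
  expect_gt(length(shared), 2)
  expect_lt(max(abs(fterm$estimate[match(shared, fterm$term)] -
                      mterm$estimate[match(shared, mterm$term)])), 1e-3)
  expect_true(all(mx$coefficients$ci_low <= mx$coefficients$odds_ratio &
                    mx$coefficients$odds_ratio <= mx$coefficients$ci_high))
})

test_that("Holm adjustment matches the hand-worked step-down", {
  expect_equal(holm_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.03, 0.06, 0.06), tolerance = 1e-9)
  expect_equal(holm_adjust(0.02), 0.02)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.04, 0.001, 0.5)
  expect_true(all(holm_adjust(p) >= p))
})

test_that("Nakagawa R-squared follows the logit-link formula", {
  expect_equal(unname(r2_glmm(0, 0)), c(0, 0))
  r <- r2_glmm(1, 1)
  expect_equal(unname(r[1]), 1 / (2 + pi^2 / 3), tolerance = 1e-9)
  expect_equal(unname(r[2]), 2 / (2 + pi^2 / 3), tolerance = 1e-9)
  r0 <- r2_glmm(0.8)
  expect_equal(unname(r0[1]), unname(r0[2]))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("stratum summaries flag significance and untrialled ranges", {
  set.seed(29)
  n <- 600
  bd <- sample(c(100, 2000), n, replace = TRUE)
  rec <- make_records(n, bd = bd)
  cats <- categorize_stim_params(rec$charge_density, rec$frequency,
                                 rec$pulse_width, rec$burst_duration)
  des <- build_transition_design(rep(1L, n), rec, cats)
  des$response <- rbinom(n - 1, 1, plogis(-0.5 + 1.2 * (bd[-n] > 500)))
  fit <- fit_fixed_logistic(des)
  tab <- summarize_stratum_fits(list(fit))
  expect_true(any(tab$note == "Not trialed"))
  expect_true(all(is.na(tab$odds_ratio[tab$note == "Not trialed"])))
  sig <- tab$significant[tab$term == "burst_duration_catbd_gt500"]
  expect_identical(sig, tab$p_holm[tab$term ==
                                     "burst_duration_catbd_gt500"] < 0.05)
  # empty / failed stratum is carried through with a reason
  tab2 <- summarize_stratum_fits(list(fit,
                                      list(stratum = "x", reason = "empty")))
  expect_true("(not estimated)" %in% tab2$term)
})
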