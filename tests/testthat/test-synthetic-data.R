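test_that("cycle intensity components follow the configured sinusoids", {
  cfg <- simulation_config(cycle_amplitudes = rep(0, 5))
  expect_true(all(simulate_cycle_intensity(cfg, 100) == 0))

  cfg1 <- simulation_config(cycle_periods = 24, cycle_amplitudes = 1,
                            cycle_phases = 0, coupling_band = 1)
  comp <- simulate_cycle_intensity(cfg1, 48)
  expect_equal(unname(comp[6, 1]), sin(pi / 2), tolerance = 1e-12)
  # deterministic
  expect_identical(comp, simulate_cycle_intensity(cfg1, 48))
})

test_that("slow cycle period is recovered by autocorrelation", {
  cfg <- simulation_config(cycle_periods = 720, cycle_amplitudes = 1,
                           cycle_phases = 0, coupling_band = 1)
  x <- simulate_cycle_intensity(cfg, 4320)[, 1]
  ac <- acf(x, lag.max = 1000, plot = FALSE)$acf[-1]
  # first local maximum beyond half a period
  peak <- which.max(ac[500:1000]) + 499
  expect_lte(abs(peak - 720), 1)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(cycle_periods = c(24, 24)),
               class = "rns_config_error")
  expect_error(simulation_config(le_rate_low = 0), class = "rns_config_error")
  expect_error(simulation_config(le_rate_low = 1, le_rate_high = 0.5),
               class = "rns_config_error")
  expect_error(simulation_config(state_dwell_low = 0.5),
               class = "rns_config_error")
  expect_error(
    simulation_config(stim_effects = list(low = c(not_a_category = 1),
                                          high = numeric(0))),
    class = "rns_config_error")
  expect_error(simulation_config(epoch_plan = list(n_epochs = 0)),
               class = "rns_config_error")
})

test_that("state chain reproduces configured dwell times", {
  n <- 60000
  cfg <- simulation_config(n_patients = 1, hours_per_patient = n,
                           state_dwell_low = 100, state_dwell_high = 100,
                           phase_coupling = 0, seed = 5)
  comp <- matrix(0, n, 5)
  cats <- categorize_stim_params(numeric(n), numeric(n), numeric(n),
                                 numeric(n))
  st <- simulate_state_chain(cfg, comp, cats, seed = 5)$states
  r <- rle(st)
  # drop censored first/last runs
  lens <- r$lengths[-c(1, length(r$lengths))]
  vals <- r$values[-c(1, length(r$values))]
  for (k in 1:2)
    expect_lt(abs(mean(lens[vals == k]) - 100) / 100, 0.15)
})

test_that("configured stimulation effects yield matching empirical odds", {
  n <- 100000
  eff <- 0.7
  cfg <- simulation_config(n_patients = 1, hours_per_patient = n,
                           state_dwell_low = 30, state_dwell_high = 30,
                           phase_coupling = 0,
                           stim_effects = list(low = numeric(0),
                                               high = c(bd_gt500 = eff)),
                           seed = 11)
  comp <- matrix(0, n, 5)
  set.seed(2)
  bd <- sample(c(100, 2000), n, replace = TRUE)
  cats <- categorize_stim_params(rep(0.5, n), rep(200, n), rep(160, n), bd)
  st <- simulate_state_chain(cfg, comp, cats, seed = 11)$states
  cur_high <- st[-n] == 2L
  y <- as.integer(st[-1] == 1L)[cur_high]
  x <- as.integer(bd[-n] > 500)[cur_high]
  se <- sqrt(sum(1 / table(x, y)))  # log-OR standard error
  expect_lt(abs(logodds_2x2(x, y) - eff), 3 * se)
  expect_gt(sum(y), 100)
})

test_that("state chain is deterministic under a fixed seed", {
  cfg <- simulation_config(n_patients = 1, hours_per_patient = 2000)
  comp <- simulate_cycle_intensity(cfg, 2000)
  cats <- categorize_stim_params(numeric(2000), numeric(2000),
                                 numeric(2000), numeric(2000))
  s1 <- simulate_state_chain(cfg, comp, cats, seed = 3)$states
  s2 <- simulate_state_chain(cfg, comp, cats, seed = 3)$states
  expect_identical(s1, s2)
  expect_error(simulate_state_chain(cfg, comp, cats[1:10, ], seed = 3),
               class = "rns_dimension_error")
})

test_that("simulated counts match configured Poisson rates", {
  n <- 10000
  cfg <- simulation_config(n_patients = 1, hours_per_patient = n,
                           iea_base_rate = 40, iea_state_bump = 0,
                           le_rate_low = 0.3, le_rate_high = 0.8)
  comp <- matrix(0, n, 5)
  states <- rep(2L, n)
  cts <- simulate_counts(states, comp, cfg, seed = 9)
  expect_true(all(cts$iea_count >= 0))
  expect_true(all(cts$le_count >= 0))
  expect_true(all(cts$iea_count == round(cts$iea_count)))
  # high-state LE mean within 3 standard errors of 0.8
  expect_lt(abs(mean(cts$le_count) - 0.8), 3 * sqrt(0.8 / n))
  # flat-cycle IEA mean within 3 standard errors of 40
  expect_lt(abs(mean(cts$iea_count) - 40), 3 * sqrt(40 / n))

  cfg_eq <- simulation_config(n_patients = 1, hours_per_patient = n,
                              le_rate_low = 0.5, le_rate_high = 0.5)
  both <- simulate_counts(c(rep(1L, n / 2), rep(2L, n / 2)), comp, cfg_eq,
                          seed = 9)
  m1 <- mean(both$le_count[1:(n / 2)])
  m2 <- mean(both$le_count[(n / 2 + 1):n])
  expect_lt(abs(m1 - m2), 3 * sqrt(2 * 0.5 / (n / 2)))
})

test_that("stimulation schedules honour the epoch plan and ranges", {
  cfg <- simulation_config(
    epoch_plan = list(n_epochs = 2, n_subperiods = 3,
                      p_midhour_change = 0.5))
  sched <- simulate_stim_schedule(cfg, 2000, seed = 4)
  expect_equal(nrow(sched), 2000)
  expect_equal(sort(unique(sched$epoch)), 1:2)
  expect_true(all(sched$b1_charge_density_uC_cm2 > 0 &
                    sched$b1_charge_density_uC_cm2 <= 9))
  ev <- attr(sched, "change_events")
  expect_true(all(diff(ev$time_h) > 0))

  # too-short epochs rejected
  expect_error(simulate_stim_schedule(cfg, 1400, seed = 4),
               class = "rns_config_error")

  # disabled hours: all parameters zero when every hour is disabled
  cfg_off <- simulation_config(
    p_stim_disabled_hour = 1,
    epoch_plan = list(n_epochs = 1, n_subperiods = 1))
  s_off <- simulate_stim_schedule(cfg_off, 800, seed = 4)
  expect_true(all(s_off$b1_charge_density_uC_cm2 == 0))
  expect_true(all(!s_off$stim_enabled))
})

test_that("charge densities drawn for a range stay inside that range", {
  # the (3, 4] category: every emitted value in (3, 4]
  set.seed(10)
  draws <- replicate(400, rnstates:::.draw_param_set()["charge_density"])
  in34 <- draws[draws > 3 & draws <= 4]
  expect_gt(length(in34), 0)
  cats <- categorize_stim_params(in34, rep(200, length(in34)),
                                 rep(160, length(in34)),
                                 rep(100, length(in34)))
  expect_true(all(cats$charge_density_cat == "cd_3_4"))
})

test_that("cohorts have the requested shape, schema and ground truth", {
  cfg <- simulation_config(n_patients = 3, hours_per_patient = 2000,
                           epoch_plan = list(n_epochs = 2,
                                             n_subperiods = 2,
                                             p_midhour_change = 0.5),
                           seed = 21)
  co <- simulate_cohort(cfg)
  expect_length(co$patients, 3)
  for (p in co$patients) {
    expect_equal(nrow(p), 2000)
    expect_true(all(p$montage %in% c("monopolar_leadtolead", "bipolar")))
    expect_true(all(p$location %in% c("mesiotemporal", "neocortical")))
  }
  for (g in co$ground_truth) {
    expect_length(g$latent_states, 2000)
    expect_true(all(g$latent_states %in% 1:2))
  }
  expect_equal(nrow(co$epochs), 6)
})

test_that("cohort CSV output is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_patients = 2, hours_per_patient = 1500,
                           epoch_plan = list(n_epochs = 1,
                                             n_subperiods = 2,
                                             p_midhour_change = 0.5),
                           seed = 33)
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  unlink(c(d1, d2), recursive = TRUE)
})
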