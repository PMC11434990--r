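test_that("Haycock BSA matches direct evaluation and scales as a power law", {
  expect_equal(haycock_bsa(47, 159), 1.435, tolerance = 1e-3)
  expect_equal(haycock_bsa(13.8, 115), 0.653, tolerance = 1e-3)
  expect_equal(haycock_bsa(4 * 20, 150), 4^0.5378 * haycock_bsa(20, 150))
  expect_error(haycock_bsa(-1, 150), "weight")
})

test_that("Quetelet BMI matches direct evaluation", {
  expect_equal(quetelet_bmi(47, 159), 47 / 1.59^2)
  expect_equal(quetelet_bmi(30, 100), 30)
  expect_equal(quetelet_bmi(2 * 25, 140), 2 * quetelet_bmi(25, 140))
})

test_that("Schwartz creatinine clearance matches direct evaluation", {
  expect_equal(schwartz_crcl(159, 0.58, k = 0.70), 0.70 * 159 / 0.58)
  expect_equal(schwartz_crcl(159, 0.58, k = 0.70), 191.9, tolerance = 1e-3)
  expect_equal(schwartz_crcl(150, 0.5, k = 0), 0)
  expect_equal(schwartz_crcl(150, 0.25, k = 0.55),
               2 * schwartz_crcl(150, 0.5, k = 0.55))
  expect_error(schwartz_crcl(150, 0), "scr")
  expect_equal(schwartz_k(c(14, 14, 8), c("M", "F", "M")),
               c(0.70, 0.55, 0.55))
})

test_that("sampled cohorts hit the target summary statistics", {
  coh <- sample_cohort(32, seed = 2024)
  expect_equal(nrow(coh), 32)
  expect_true(median(coh$age) > 11 && median(coh$age) < 15)
  expect_true(median(coh$bsa) > 1.3 && median(coh$bsa) < 1.6)
  expect_true(all(coh$age >= 5 & coh$age <= 18))
  expect_true(all(coh$weight >= 13.8 & coh$weight <= 85.5))
  expect_true(all(coh$height >= 115 & coh$height <= 177))
  expect_true(all(coh$baseline_scr >= 0.17 & coh$baseline_scr <= 3.2))
  # derived columns are recomputable, never drawn
  expect_equal(coh$bsa, haycock_bsa(coh$weight, coh$height))
  expect_equal(coh$bmi, quetelet_bmi(coh$weight, coh$height))
  expect_equal(coh$crcl, schwartz_crcl(coh$height, coh$baseline_scr,
                                       schwartz_k(coh$age, coh$sex)))
})

test_that("point-mass configuration yields exactly the configured patient", {
  cfg <- cohort_config(age = list(fixed = 13, min = 5, max = 18),
                       height = list(fixed = 159),
                       bmi = list(fixed = 47),       # fixed weight (kg)
                       scr = list(fixed = 0.58, range = c(0.17, 3.2),
                                  sdlog_within = 0),
                       cycles = list(fixed = 3))
  coh <- sample_cohort(2, config = cfg, seed = 1)
  expect_equal(coh$age, c(13, 13))
  expect_equal(coh$weight, c(47, 47))
  expect_equal(coh$height, c(159, 159))
  expect_equal(coh$baseline_scr, c(0.58, 0.58))
  expect_equal(coh$n_cycles, c(3L, 3L))
  expect_equal(coh$bsa, rep(haycock_bsa(47, 159), 2))
})

test_that("cohort sampling is deterministic under a seed", {
  expect_identical(sample_cohort(20, seed = 77), sample_cohort(20, seed = 77))
})

test_that("impossible truncation bounds are a configuration error", {
  expect_error(cohort_config(scr = list(range = c(3, 1))), "truncation")
})

test_that("simulated trials emulate the study scale", {
  coh <- sample_cohort(32, seed = 101)
  d <- simulate_trial(coh, model = final_mtx_model(), seed = 202)
  n_cycles <- nrow(unique(d[d$EVID == 1, c("ID", "OCC")]))
  n_obs <- sum(d$EVID == 0)
  expect_equal(n_cycles, sum(coh$n_cycles))
  expect_gt(n_cycles, 170)
  expect_lt(n_cycles, 260)
  expect_gt(n_obs, 430)
  expect_lt(n_obs, 700)
  obs_per_cycle <- table(paste(d$ID, d$OCC)[d$EVID == 0])
  expect_true(all(obs_per_cycle >= 2 & obs_per_cycle <= 6))
  # the generator's own inclusion filter is a no-op
  f <- apply_inclusion_filters(d, quiet = TRUE)
  expect_equal(nrow(f), nrow(d))
  expect_equal(attr(f, "exclusions")$obs_beyond_window, 0)
  # determinism
  d2 <- simulate_trial(coh, model = final_mtx_model(), seed = 202)
  expect_equal(d2$DV, d$DV)
})

test_that("zero-variability simulation reproduces the typical profile exactly", {
  m0 <- noise_free_model()
  cfg <- cohort_config(cycles = list(fixed = 2),
                       scr = list(base = 0.25, slope = 0.025,
                                  sdlog_between = 0.4, sdlog_within = 0,
                                  range = c(0.17, 3.2)))
  coh <- sample_cohort(4, config = cfg, seed = 9)
  d <- simulate_trial(coh, model = m0, config = cfg, seed = 10)
  obs <- d[d$EVID == 0, ]
  for (i in seq_len(nrow(obs))) {
    r <- obs[i, ]
    dose <- d[d$EVID == 1 & d$ID == r$ID & d$OCC == r$OCC, ]
    ip <- individual_parameters(m0, scr = r$SCR, bsa = r$BSA)
    f <- conc_2cpt(r$TIME, dose_events(dose$TIME, dose$AMT, dose$DUR),
                   ip$cl, ip$vc, ip$q, ip$vp)
    expect_equal(r$DV, f, tolerance = 1e-12)
  }
})

test_that("sampling-time imputation subtracts the mean arrival offset", {
  # numeric hours: arrival 10:00 with a 32.5 min offset -> 09:27.5
  pairs <- data.frame(arrival = c(10, 11, 12),
                      sampling = c(10, 11, 12) - c(30, 32.5, 35) / 60)
  out <- impute_sample_time(10, pairs = pairs)
  expect_equal(attr(out, "offset_min"), 32.5)
  expect_equal(as.numeric(out), 10 - 32.5 / 60)
  expect_equal(as.numeric(impute_sample_time(10, mean_offset_min = 0)), 10)
  expect_error(impute_sample_time(10, pairs = data.frame(arrival = numeric(),
                                                         sampling = numeric())),
               "no complete")
  # POSIXct arithmetic
  arr <- as.POSIXct("2023-01-01 10:00:00", tz = "UTC")
  out2 <- impute_sample_time(arr, mean_offset_min = 32.5)
  expect_equal(as.numeric(difftime(arr, out2, units = "mins")), 32.5)
})

test_that("imputation error is centred at zero on synthetic records", {
  set.seed(31)
  true_sampling <- runif(300, 0, 24)
  offsets <- rnorm(300, mean = 32.5, sd = 4.7) / 60
  arrival <- true_sampling + offsets
  known <- sample(300, 150)
  est <- impute_sample_time(arrival[-known],
                            pairs = data.frame(arrival = arrival[known],
                                               sampling = true_sampling[known]))
  err <- (as.numeric(est) - true_sampling[-known]) * 60
  expect_lt(abs(mean(err)), 1.5)  # minutes
})
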