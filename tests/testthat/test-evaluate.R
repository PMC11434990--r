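test_that("prediction errors match hand computation", {
  r <- prediction_errors(c(13, 8), c(10, 10))
  expect_equal(r$pe, c(30, -20))
  expect_equal(r$mpe, 5)
  expect_equal(r$rmse, sqrt(650))
  expect_equal(r$f20, 50)
  expect_equal(r$f30, 100)
  expect_equal(r$mape, 5)  # median of signed PE, the printed definition
  r2 <- prediction_errors(c(13, 8), c(10, 10), mape_absolute = TRUE)
  expect_equal(r2$mape, 25)
})

test_that("perfect predictions give the all-zero report", {
  obs <- c(0.2, 1.5, 4.8)
  r <- prediction_errors(obs, obs)
  expect_equal(r$pe, c(0, 0, 0))
  expect_equal(c(r$mpe, r$mape, r$rmse), c(0, 0, 0))
  expect_equal(c(r$f20, r$f30), c(100, 100))
  expect_true(r$acceptable)
})

test_that("prediction errors equal a brute-force recomputation on random vectors", {
  set.seed(77)
  for (i in 1:5) {
    n <- sample(3:40, 1)
    obs <- runif(n, 0.05, 20)
    pred <- obs * exp(rnorm(n, 0, 0.5))
    r <- prediction_errors(pred, obs)
    pe <- numeric(n)
    for (j in 1:n) pe[j] <- 100 * (pred[j] - obs[j]) / obs[j]
    expect_equal(r$pe, pe)
    expect_equal(r$mpe, sum(pe) / n)
    expect_equal(r$rmse, sqrt(sum(pe^2) / n))
    expect_equal(r$f20, 100 * sum(abs(pe) <= 20) / n)
    expect_equal(r$f30, 100 * sum(abs(pe) <= 30) / n)
    # invariants
    expect_gte(r$rmse, abs(r$mpe) - 1e-12)
    expect_lte(r$f20, r$f30)
  }
})

test_that("the acceptability verdict implements the clinical rule", {
  # F20 >= 35, F30 >= 50, |MPE| <= 30, RMSE <= 30
  good <- prediction_errors(c(1.1, 0.95, 1.02, 0.9), c(1, 1, 1, 1))
  expect_true(good$acceptable)
  biased <- prediction_errors(rep(3, 10), rep(1, 10))
  expect_false(biased$acceptable)
  expect_false(biased$criteria[["mpe"]])
  # F20 just under the bar fails even with fine MPE/RMSE
  mixed <- prediction_errors(c(rep(1.25, 7), rep(1, 3)), rep(1, 10))
  expect_false(mixed$criteria[["f20"]])
})

test_that("input validation on prediction errors", {
  expect_error(prediction_errors(1, c(1, 2)), "equal")
  expect_error(prediction_errors(c(1, 2), c(1, 0)), "positive")
})

test_that("external evaluation is self-consistent and catches misspecification", {
  # at low variability, evaluating the generating model against its own
  # simulated data must be near-unbiased and clinically acceptable at both
  # levels (machinery correctness)
  m_low <- final_mtx_model()
  m_low$bsv_cl <- m_low$bsv_vc <- 0.05
  m_low$corr_cl_vc <- 0
  m_low$bov_cl <- 0.05
  m_low$sigma_prop <- 0.1
  d_low <- small_sim_dataset(n = 10, cycles = 2, seed = 19, model = m_low)
  ev_low <- evaluate_external_model(m_low, d_low)
  expect_lt(abs(ev_low$population$mpe), 15)
  expect_true(ev_low$acceptable)
  expect_gt(ev_low$individual$f30, 50)
  # at the published variability the steep post-infusion decay makes the
  # *mean* PE of population predictions blow up through the upper tail,
  # while the median stays moderate and MAP-based individual predictions
  # still track the observations
  m <- final_mtx_model()
  d <- small_sim_dataset(n = 10, cycles = 2, seed = 19)
  ev <- evaluate_external_model(m, d)
  expect_lt(abs(ev$population$mape), 40)  # median PE
  expect_gt(ev$individual$f30, 50)
  # a model with clearance misspecified 3x low predicts systematically high
  bad <- m
  bad$tvcl <- m$tvcl / 3
  ev_bad <- evaluate_external_model(bad, d)
  expect_gt(ev_bad$population$mpe, 100)
  expect_false(ev_bad$acceptable)
})

test_that("one observation equal to its prediction yields the all-zero report", {
  m0 <- noise_free_model()
  amt <- 12 * 1.45 * 1000
  ip <- individual_parameters(m0, scr = 0.58, bsa = 1.45)
  f <- conc_2cpt(28, dose_events(0, amt, 4), ip$cl, ip$vc, ip$q, ip$vp)
  d <- as_mtx_dataset(data.frame(
    ID = 1, OCC = 1, TIME = c(0, 28), EVID = c(1L, 0L),
    AMT = c(amt, NA), DUR = c(4, NA), DV = c(NA, f),
    SCR = 0.58, BSA = 1.45))
  ev <- evaluate_external_model(m0, d)
  expect_equal(ev$population$pe, 0, tolerance = 1e-10)
  expect_equal(ev$individual$rmse, 0, tolerance = 1e-8)
})

test_that("a missing required covariate is reported by name", {
  m <- final_mtx_model()
  d <- small_sim_dataset(n = 2, cycles = 1, seed = 23)
  d$SCR <- NULL
  expect_error(evaluate_external_model(m, as_mtx_dataset(as.data.frame(d))),
               "SCR")
})

test_that("degenerate VPC reduces to the typical profile and is seed-stable", {
  m0 <- noise_free_model()
  cfg <- cohort_config(cycles = list(fixed = 1),
                       scr = list(base = 0.25, slope = 0.025,
                                  sdlog_between = 0.3, sdlog_within = 0,
                                  range = c(0.17, 3.2)))
  coh <- sample_cohort(5, config = cfg, seed = 41)
  d <- simulate_trial(coh, model = m0, config = cfg, seed = 42)
  v <- vpc(d, m0, n_sim = 1, seed = 1)
  for (pb in v$per_bin) {
    # all percentiles of a deterministic simulation coincide, and the
    # "observations" (noise-free) sit exactly on them
    expect_equal(pb$sim_q_lo, pb$sim_q_hi, tolerance = 1e-12)
    expect_equal(sort(pb$obs_q), sort(pb$pooled_q), tolerance = 1e-9)
  }
  m <- final_mtx_model()
  v1 <- vpc(d, m, n_sim = 20, seed = 7)
  v2 <- vpc(d, m, n_sim = 20, seed = 7)
  expect_equal(v1$per_bin, v2$per_bin)
  expect_equal(v1$coverage, v2$coverage)
})

test_that("VPC percentile presets and band nesting", {
  d <- small_sim_dataset(n = 6, cycles = 1, seed = 47)
  m <- final_mtx_model()
  v <- vpc(d, m, n_sim = 30, percentiles = "p10_90", seed = 3)
  expect_equal(v$percentiles, c(10, 50, 90))
  for (pb in v$per_bin) {
    expect_true(all(diff(pb$pooled_q) >= 0))
    expect_true(all(diff(pb$sim_q_median) >= 0))
  }
})

test_that("VPC bands widen with larger variability", {
  d <- small_sim_dataset(n = 8, cycles = 1, seed = 53)
  m <- final_mtx_model()
  m_small <- m
  m_small$bsv_cl <- 0.05; m_small$bsv_vc <- 0.05; m_small$bov_cl <- 0.05
  m_small$sigma_prop <- 0.1
  v_big <- vpc(d, m, n_sim = 60, seed = 11)
  v_small <- vpc(d, m_small, n_sim = 60, seed = 11)
  width <- function(v) mean(vapply(v$per_bin, function(pb) {
    log(pb$pooled_q[3] / pb$pooled_q[1])
  }, 0))
  expect_gt(width(v_big), width(v_small))
})

test_that("CWRES are near zero for noise-free data and calibrated under the model", {
  m0 <- noise_free_model()
  m0$sigma_prop <- 0.05   # finite residual scale, data still noise-free
  d0 <- tiny_dataset()
  g0 <- gof_tables(m0, d0)
  expect_lt(max(abs(g0$table$CWRES)), 0.05)
  expect_lt(max(abs(g0$table$IWRES)), 1e-6)
  # under the generating model CWRES should be roughly standard normal
  m <- final_mtx_model()
  d <- small_sim_dataset(n = 16, cycles = 3, seed = 83)
  g <- gof_tables(m, d)
  expect_lt(abs(mean(g$table$CWRES)), 0.3)
  expect_gt(sd(g$table$CWRES), 0.6)
  expect_lt(sd(g$table$CWRES), 1.5)
  # doubling sigma roughly halves the residual spread
  m2 <- m
  m2$sigma_prop <- 2 * m$sigma_prop
  g2 <- gof_tables(m2, d)
  expect_lt(sd(g2$table$CWRES), sd(g$table$CWRES) * 0.85)
})
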