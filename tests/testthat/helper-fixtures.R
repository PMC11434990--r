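# Shared fixtures, all built in code.

# deterministic model without random effects / residual noise
noise_free_model <- function() {
  mtx_model(tvcl = 14.8, tvvc = 82.5, tvq = 0.178, tvvp = 5.72,
            theta_scr = -0.192, theta_bsa = 0.301,
            bsv_cl = 0, bsv_vc = 0, corr_cl_vc = 0, bov_cl = 0,
            sigma_prop = 0)
}

# a tiny hand-built two-subject dataset (one or two cycles, sparse samples)
tiny_dataset <- function(model = noise_free_model(), eta = c(0, 0),
                         kappa = 0) {
  rows <- list()
  for (id in 1:2) {
    scr <- c(0.5, 0.9)[id]
    bsa <- c(1.2, 1.6)[id]
    amt <- 12 * bsa * 1000
    ip <- individual_parameters(model, scr = scr, bsa = bsa,
                                eta = eta, kappa = kappa)
    tt <- c(28, 52, 76)
    f <- conc_2cpt(tt, dose_events(0, amt, 4), ip$cl, ip$vc, ip$q, ip$vp)
    rows[[id]] <- data.frame(
      ID = id, OCC = 1L, TIME = c(0, tt), EVID = c(1L, 0L, 0L, 0L),
      AMT = c(amt, NA, NA, NA), DUR = c(4, NA, NA, NA),
      DV = c(NA, f), SCR = scr, BSA = bsa)
  }
  as_mtx_dataset(do.call(rbind, rows))
}

# moderately sized simulated dataset for estimation tests
small_sim_dataset <- function(n = 8, cycles = 2, seed = 42,
                              model = final_mtx_model()) {
  cfg <- cohort_config(cycles = list(fixed = cycles))
  coh <- sample_cohort(n, config = cfg, seed = seed)
  simulate_trial(coh, model = model, config = cfg, seed = seed + 1)
}
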