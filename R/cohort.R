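#' Anthropometric support equations
#'
#' Body surface area by the Haycock formula
#' \eqn{BSA = 0.024265\, W^{0.5378} H^{0.3964}} (W in kg, H in cm), body mass
#' index by the Quetelet formula \eqn{W / (H/100)^2}, and creatinine
#' clearance by the Schwartz formula \eqn{k \cdot H / SCr}
#' (mL/min/1.73 m^2).
#'
#' @param weight body weight (kg), positive.
#' @param height body height (cm), positive.
#' @return numeric vector.
#' @export
haycock_bsa <- function(weight, height) {
  if (any(!is.finite(weight) | weight <= 0)) stop("weight must be positive")
  if (any(!is.finite(height) | height <= 0)) stop("height must be positive")
  0.024265 * weight^0.5378 * height^0.3964
}

#' @rdname haycock_bsa
#' @export
quetelet_bmi <- function(weight, height) {
  if (any(!is.finite(weight) | weight <= 0)) stop("weight must be positive")
  if (any(!is.finite(height) | height <= 0)) stop("height must be positive")
  weight / (height / 100)^2
}

#' @rdname haycock_bsa
#' @param scr serum creatinine (mg/dL), positive.
#' @param k Schwartz proportionality constant; see [schwartz_k()].
#' @export
schwartz_crcl <- function(height, scr, k = 0.55) {
  if (any(!is.finite(scr) | scr <= 0)) stop("scr must be positive")
  if (any(!is.finite(height) | height <= 0)) stop("height must be positive")
  k * height / scr
}

#' Schwartz constant by age and sex
#'
#' Original Schwartz constants: 0.45 below 1 year, 0.55 for children and
#' adolescent females, 0.70 for adolescent males (>= 13 years). These are
#' the constants consistent with a creatinine-clearance cohort median near
#' 190 mL/min/1.73 m^2 in an adolescent-heavy population (the revised
#' bedside constant 0.413 is not).
#'
#' @param age years.
#' @param sex `"M"` or `"F"` (recycled).
#' @return numeric vector of constants.
#' @export
schwartz_k <- function(age, sex = "M") {
  sex <- rep_len(sex, length(age))
  ifelse(age < 1, 0.45, ifelse(age >= 13 & sex == "M", 0.70, 0.55))
}

#' Trial design for the monitored HDMTX protocol
#'
#' Describes the dosing and sparse sampling scheme: 4-h intravenous
#' infusions of a per-m^2 dose, sparse therapeutic-monitoring samples at
#' nominal 24/48/72/96 h after the end of infusion, and 2-6 samples per
#' cycle. Cycle spacing defaults to 2 weeks; carryover between cycles is
#' negligible at this spacing given the terminal half-life.
#'
#' @param dose_per_m2 protocol dose (g/m^2).
#' @param infusion_hours infusion duration (h).
#' @param cycle_spacing_h spacing between cycle starts (h).
#' @param nominal_times nominal sampling times (h after end of infusion),
#'   all <= 96.
#' @param samples_per_cycle integer range `c(min, max)` within 2..6.
#' @param sample_n_probs probabilities for each sample count from
#'   `samples_per_cycle[1]` to `samples_per_cycle[2]` (median 3 by default).
#' @param time_jitter_sd_min SD of sampling-time jitter (minutes).
#' @param dose_gm2_mean,dose_gm2_sd,dose_gm2_range per-cycle realized dose
#'   (g/m^2): truncated normal around the cohort median dose (set `sd = 0`
#'   for the fixed protocol dose).
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(dose_per_m2 = 12, infusion_hours = 4,
                         cycle_spacing_h = 336,
                         nominal_times = c(24, 48, 72, 96),
                         samples_per_cycle = c(2, 6),
                         sample_n_probs = c(0.45, 0.40, 0.10, 0.03, 0.02),
                         time_jitter_sd_min = 30,
                         dose_gm2_mean = 11.9, dose_gm2_sd = 1.0,
                         dose_gm2_range = c(5.9, 12.9)) {
  if (any(nominal_times > 96)) stop("nominal sampling times must be <= 96 h")
  if (samples_per_cycle[1] < 2 || samples_per_cycle[2] > 6 ||
      samples_per_cycle[1] > samples_per_cycle[2]) {
    stop("samples_per_cycle must be a range within [2, 6]")
  }
  nk <- samples_per_cycle[2] - samples_per_cycle[1] + 1L
  if (length(sample_n_probs) != nk) {
    stop("sample_n_probs must have one entry per sample count")
  }
  structure(list(dose_per_m2 = dose_per_m2, infusion_hours = infusion_hours,
                 cycle_spacing_h = cycle_spacing_h,
                 nominal_times = sort(nominal_times),
                 samples_per_cycle = samples_per_cycle,
                 sample_n_probs = sample_n_probs / sum(sample_n_probs),
                 time_jitter_sd_min = time_jitter_sd_min,
                 dose_gm2_mean = dose_gm2_mean, dose_gm2_sd = dose_gm2_sd,
                 dose_gm2_range = dose_gm2_range),
            class = "trial_design")
}

#' Demographic configuration for the virtual cohort
#'
#' Target distributions chosen to reproduce the summary statistics of the
#' study cohort (32 patients aged 5-18, median 13.25 y; weight 13.8-85.5 kg;
#' height 115-177 cm; SCr median 0.58 mg/dL, range 0.17-3.2): age from a
#' scaled Beta skewed toward adolescence; height from a piecewise-linear
#' growth curve in age with sex offset and noise; weight through an
#' age-dependent BMI; baseline SCr log-normal around an age-dependent
#' median. Each block accepts a `fixed` entry giving a degenerate
#' (point-mass) value, used for deterministic designs. BSA, BMI and CrCL
#' are always computed from weight/height/SCr, never drawn.
#'
#' @param age,height,bmi,scr,cycles distribution blocks (lists); see
#'   defaults for the recognized fields.
#' @param p_male probability of male sex.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(
    age = list(min = 5, max = 18, shape1 = 1.8, shape2 = 1.1),
    height = list(intercept = 116, slope = 5.4, plateau_age = 16.5,
                  sex_effect = 4, sd = 6, range = c(115, 177)),
    bmi = list(base = 15.5, slope = 0.35, sdlog = 0.15,
               weight_range = c(13.8, 85.5)),
    scr = list(base = 0.25, slope = 0.025, sdlog_between = 0.4,
               sdlog_within = 0.25, range = c(0.17, 3.2)),
    cycles = list(mean = 6.75, min = 1, max = 12),
    p_male = 18 / 32) {
  cfg <- structure(list(age = age, height = height, bmi = bmi, scr = scr,
                        cycles = cycles, p_male = p_male),
                   class = "cohort_config")
  for (blk in c("height", "bmi", "scr")) {
    rng <- cfg[[blk]]$range %||% cfg[[blk]]$weight_range
    if (!is.null(rng) && rng[1] >= rng[2]) {
      stop("impossible truncation bounds in '", blk, "' block")
    }
  }
  cfg
}

# truncated sampling by redraw; `draw(idx)` must return draws for exactly
# the requested element indices (so per-element means stay aligned)
rtrunc <- function(n, draw, lower, upper, max_tries = 1000) {
  x <- draw(seq_len(n))
  for (i in seq_len(max_tries)) {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) return(x)
    x[bad] <- draw(bad)
  }
  pmin(pmax(x, lower), upper)
}

#' Generate a virtual patient cohort
#'
#' Draws demographics from the configured truncated distributions and
#' computes BSA (Haycock), BMI (Quetelet) and CrCL (Schwartz, age/sex
#' constant) from them.
#'
#' @param n_patients number of patients (>= 1).
#' @param design a [trial_design()].
#' @param config a [cohort_config()].
#' @param seed optional integer seed.
#' @return data.frame of class `virtual_cohort` with one row per patient:
#'   `id`, `sex`, `age`, `weight`, `height`, `bsa`, `bmi`, `baseline_scr`,
#'   `crcl`, `n_cycles`.
#' @export
sample_cohort <- function(n_patients, design = trial_design(),
                          config = cohort_config(), seed = NULL) {
  stopifnot(n_patients >= 1)
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  fixed_or <- function(blk, draw) {
    if (!is.null(blk$fixed)) rep(blk$fixed, n_patients) else draw()
  }
  age <- fixed_or(cfg$age, function() {
    cfg$age$min + (cfg$age$max - cfg$age$min) *
      stats::rbeta(n_patients, cfg$age$shape1, cfg$age$shape2)
  })
  sex <- if (!is.null(cfg$p_male) && is.numeric(cfg$p_male)) {
    ifelse(stats::runif(n_patients) < cfg$p_male, "M", "F")
  } else rep("M", n_patients)
  height <- fixed_or(cfg$height, function() {
    mu <- cfg$height$intercept +
      cfg$height$slope * (pmin(age, cfg$height$plateau_age) - cfg$age$min) +
      ifelse(sex == "M", 1, -1) * cfg$height$sex_effect / 2
    rtrunc(n_patients, function(idx) {
      stats::rnorm(length(idx), mu[idx], cfg$height$sd)
    }, cfg$height$range[1], cfg$height$range[2])
  })
  weight <- fixed_or(cfg$bmi, function() {
    mu_bmi <- cfg$bmi$base + cfg$bmi$slope * (age - cfg$age$min)
    w <- mu_bmi * (height / 100)^2 *
      exp(stats::rnorm(n_patients, 0, cfg$bmi$sdlog))
    pmin(pmax(w, cfg$bmi$weight_range[1]), cfg$bmi$weight_range[2])
  })
  scr <- fixed_or(cfg$scr, function() {
    med <- cfg$scr$base + cfg$scr$slope * age
    rtrunc(n_patients, function(idx) {
      med[idx] * exp(stats::rnorm(length(idx), 0, cfg$scr$sdlog_between))
    }, cfg$scr$range[1], cfg$scr$range[2])
  })
  n_cycles <- fixed_or(cfg$cycles, function() {
    pmin(pmax(stats::rpois(n_patients, cfg$cycles$mean), cfg$cycles$min),
         cfg$cycles$max)
  })
  out <- data.frame(
    id = seq_len(n_patients), sex = sex, age = age,
    weight = weight, height = height,
    bsa = haycock_bsa(weight, height),
    bmi = quetelet_bmi(weight, height),
    baseline_scr = scr,
    crcl = schwartz_crcl(height, scr, schwartz_k(age, sex)),
    n_cycles = as.integer(n_cycles)
  )
  class(out) <- c("virtual_cohort", "data.frame")
  out
}

#' Simulate a sparse TDM trial
#'
#' Generates a complete monitoring dataset for a virtual cohort under a
#' trial design and a generating population model: per patient one
#' \eqn{\eta} pair; per cycle a realized dose (g/m^2 x BSA, 4-h infusion), a
#' fresh \eqn{\kappa}, a cycle serum creatinine (log-normal around the
#' patient baseline), jittered sparse sampling times, and proportional
#' residual error (positive by redraw). The output satisfies the study
#' inclusion rules (at least 2 observations per cycle, none beyond 96 h
#' after the end of infusion) by construction.
#'
#' @param cohort a `virtual_cohort` from [sample_cohort()].
#' @param design a [trial_design()].
#' @param model the generating `mtx_model`.
#' @param config the [cohort_config()] used for within-cycle SCr variation.
#' @param seed optional integer seed.
#' @return an `mtx_dataset` (see [as_mtx_dataset()]).
#' @export
simulate_trial <- function(cohort, design = trial_design(),
                           model = final_mtx_model(),
                           config = cohort_config(), seed = NULL) {
  stopifnot(inherits(cohort, "virtual_cohort"), inherits(model, "mtx_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  re <- draw_random_effects(model, n, cohort$n_cycles)
  jit_sd <- design$time_jitter_sd_min / 60
  rows <- vector("list", n)
  nn <- seq(design$samples_per_cycle[1], design$samples_per_cycle[2])
  for (i in seq_len(n)) {
    p <- cohort[i, ]
    cyc <- vector("list", p$n_cycles)
    for (k in seq_len(p$n_cycles)) {
      start <- (k - 1) * design$cycle_spacing_h
      gm2 <- if (design$dose_gm2_sd > 0) {
        rtrunc(1, function(idx) stats::rnorm(length(idx),
                                             design$dose_gm2_mean,
                                             design$dose_gm2_sd),
               design$dose_gm2_range[1], design$dose_gm2_range[2])
      } else design$dose_per_m2
      amt <- gm2 * p$bsa * 1000
      scr_k <- if (!is.null(config$scr$fixed)) config$scr$fixed else {
        rtrunc(1, function(idx) p$baseline_scr *
                 exp(stats::rnorm(length(idx), 0, config$scr$sdlog_within)),
               config$scr$range[1], config$scr$range[2])
      }
      k_samp <- sample(nn, 1, prob = design$sample_n_probs)
      tpost <- design$nominal_times[seq_len(min(k_samp, length(design$nominal_times)))]
      if (k_samp > length(design$nominal_times)) {
        extra <- sample(utils::tail(design$nominal_times, 2),
                        k_samp - length(design$nominal_times), replace = TRUE)
        tpost <- c(tpost, extra)
      }
      tpost <- sort(pmin(pmax(tpost + stats::rnorm(k_samp, 0, jit_sd),
                              design$infusion_hours + 1), 96))
      ip <- individual_parameters(model, scr = scr_k, bsa = p$bsa,
                                  eta = re$eta[i, ], kappa = re$kappa[[i]][k])
      tobs <- start + design$infusion_hours + tpost
      f <- conc_2cpt(tobs, dose_events(start, amt, design$infusion_hours),
                     ip$cl, ip$vc, ip$q, ip$vp)
      y <- add_residual_error(f, model$sigma_prop)
      cyc[[k]] <- data.frame(
        ID = p$id, OCC = k,
        TIME = c(start, tobs),
        EVID = c(1L, rep(0L, k_samp)),
        AMT = c(amt, rep(NA_real_, k_samp)),
        DUR = c(design$infusion_hours, rep(NA_real_, k_samp)),
        DV = c(NA_real_, as.numeric(y)),
        SCR = scr_k, BSA = p$bsa, WT = p$weight, HT = p$height,
        AGE = p$age, SEX = p$sex
      )
    }
    rows[[i]] <- do.call(rbind, cyc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  as_mtx_dataset(out)
}

#' Sampling-time imputation from laboratory arrival times
#'
#' When the drawing time of a monitoring sample is missing, it is imputed as
#' the laboratory arrival time minus the mean arrival-minus-sampling offset
#' estimated from records where both times are known (single imputation).
#'
#' @param arrival arrival time(s): `POSIXct`, or numeric hours.
#' @param mean_offset_min known mean offset in minutes; if `NULL`, estimated
#'   from `pairs`.
#' @param pairs data.frame with columns `arrival` and `sampling` (same type
#'   as `arrival`) used to estimate the offset.
#' @return imputed sampling time(s), same type as `arrival`; the estimated
#'   offset (minutes) is attached as attribute `"offset_min"`.
#' @export
impute_sample_time <- function(arrival, mean_offset_min = NULL, pairs = NULL) {
  if (is.null(mean_offset_min)) {
    if (is.null(pairs) || !nrow(pairs)) {
      stop("no complete arrival/sampling records to estimate the offset")
    }
    d <- if (inherits(pairs$arrival, "POSIXct")) {
      as.numeric(difftime(pairs$arrival, pairs$sampling, units = "mins"))
    } else {
      (pairs$arrival - pairs$sampling) * 60
    }
    d <- d[is.finite(d)]
    if (!length(d)) stop("no complete arrival/sampling records to estimate the offset")
    mean_offset_min <- mean(d)
  }
  out <- if (inherits(arrival, "POSIXct")) {
    arrival - mean_offset_min * 60
  } else {
    arrival - mean_offset_min / 60
  }
  structure(out, offset_min = mean_offset_min)
}
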