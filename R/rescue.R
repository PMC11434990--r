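#' Methotrexate molecular weight (g/mol)
#'
#' Used for all micromolar / mg/L conversions; with one-decimal rounding it
#' reproduces every printed mg/L threshold of the monitoring protocol.
#' @export
MTX_MW <- 454.44

#' Unit conversion between micromolar and mg/L
#'
#' \eqn{mg/L = \mu M \times MW / 1000} with MW = 454.44 g/mol.
#'
#' @param c concentration(s), non-negative.
#' @param round_dp optional decimal places for protocol-table style
#'   rounding.
#' @return converted concentration(s).
#' @export
umol_to_mgl <- function(c, round_dp = NULL) {
  if (any(c < 0)) stop("concentration must be non-negative")
  out <- c * MTX_MW / 1000
  if (!is.null(round_dp)) out <- round(out, round_dp)
  out
}

#' @rdname umol_to_mgl
#' @export
mgl_to_umol <- function(c, round_dp = NULL) {
  if (any(c < 0)) stop("concentration must be non-negative")
  out <- c * 1000 / MTX_MW
  if (!is.null(round_dp)) out <- round(out, round_dp)
  out
}

#' Toxicity thresholds and leucovorin regimens of the monitoring protocol
#'
#' Checkpoints at 24/48/72 h after the end of infusion. Target
#' concentrations lie strictly below the lower bound; the moderate band is
#' inclusive at both printed endpoints; severe is strictly above the upper
#' bound. Bounds are carried both in micromolar and in the printed mg/L
#' values (one-decimal conversions); classification uses the printed mg/L
#' bounds. Leucovorin (LCV) regimens escalate with the toxicity class and
#' differ between the first 24 h and later rescue.
#'
#' @return list of class `toxicity_rules` with elements `thresholds`
#'   (data.frame: checkpoint_h, target_below_um / moderate_upper_um and the
#'   mg/L equivalents) and `lcv` (data.frame: phase, class, regimen, and
#'   structured dose/route/interval/stop-rule fields).
#' @export
botg_rules <- function() {
  thresholds <- data.frame(
    checkpoint_h = c(24, 48, 72),
    target_below_um = c(10, 2, 0.3),
    moderate_upper_um = c(50, 5, 1),
    target_below_mgl = umol_to_mgl(c(10, 2, 0.3), round_dp = 1),
    moderate_upper_mgl = umol_to_mgl(c(50, 5, 1), round_dp = 1)
  )
  lcv <- data.frame(
    phase = rep(c("first24h", "after24h"), each = 3),
    class = rep(c("target", "moderate", "severe"), 2),
    dose_mg = c(15, 30, 150, 15, 30, 15),
    route = c("i.v. bolus", "i.v. bolus", "i.v.", "p.o.", "p.o.", "i.v."),
    interval_h = c(NA, NA, 3, 6, 6, 3),
    stop_rule = c(NA, NA, "until 1 uM", NA, NA, NA),
    regimen = c("15 mg i.v. bolus", "30 mg i.v. bolus",
                "150 mg i.v. q3 h (until 1 uM)",
                "15 mg p.o. q6 h", "30 mg p.o. q6 h", "15 mg i.v. q3 h")
  )
  structure(list(thresholds = thresholds, lcv = lcv),
            class = "toxicity_rules")
}

classify_one <- function(c, lower, upper) {
  if (is.na(c)) return(NA_character_)
  if (c < lower) "target" else if (c <= upper) "moderate" else "severe"
}

#' Classify methotrexate toxicity and recommend leucovorin rescue
#'
#' Classifies each monitoring checkpoint against the protocol bands and
#' attaches the leucovorin regimen for the worst (overall) class, for both
#' the first-24-h and the later rescue phase. Raising any concentration
#' never lowers a class (monotonicity).
#'
#' @param c24,c48,c72 concentrations (mg/L) at 24/48/72 h after the end of
#'   infusion; `NA` allowed for unmeasured checkpoints.
#' @param rules a [botg_rules()] rule set.
#' @return object of class `toxicity_assessment`: `checkpoints` (data.frame
#'   with concentration and class per checkpoint), `overall` class, and
#'   `lcv` (the recommended regimens, structured).
#' @export
classify_toxicity <- function(c24, c48 = NA, c72 = NA, rules = botg_rules()) {
  conc <- c(c24, c48, c72)
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  th <- rules$thresholds
  cls <- vapply(1:3, function(i) {
    classify_one(conc[i], th$target_below_mgl[i], th$moderate_upper_mgl[i])
  }, "")
  lev <- c("target", "moderate", "severe")
  overall <- lev[max(c(1, match(cls, lev)), na.rm = TRUE)]
  lcv <- rules$lcv[rules$lcv$class == overall, , drop = FALSE]
  structure(list(
    checkpoints = data.frame(checkpoint_h = th$checkpoint_h,
                             concentration_mgl = conc, class = cls),
    overall = overall, lcv = lcv),
    class = "toxicity_assessment")
}

#' @export
print.toxicity_assessment <- function(x, ...) {
  cat("Toxicity assessment (mg/L):\n")
  print(x$checkpoints)
  cat("overall class:", x$overall, "\n")
  cat("LCV rescue: first 24 h:", x$lcv$regimen[x$lcv$phase == "first24h"],
      "| after 24 h:", x$lcv$regimen[x$lcv$phase == "after24h"], "\n")
  invisible(x)
}

#' Is monitoring complete?
#'
#' Monitoring continues until the methotrexate level is at or below 0.3
#' micromolar (exact conversion, 0.136332 mg/L -- not the rounded table
#' value).
#'
#' @param c concentration (mg/L), non-negative.
#' @return logical.
#' @export
monitoring_complete <- function(c) {
  if (any(c < 0)) stop("concentration must be non-negative")
  c <= umol_to_mgl(0.3)
}

#' Pediatric reference serum creatinine by age band
#'
#' Normal-renal-function reference SCr values by age band. The exact
#' guidance table is not part of the packaged study output; these defaults
#' are literature-based upper-normal values for the two simulation age
#' groups (5-10 years and above 10 years) and are an editable external
#' assumption -- pass your own table where institutional references exist.
#'
#' @return data.frame with `age_min`, `age_max` (years) and `ref_scr`
#'   (mg/dL).
#' @export
reference_scr_table <- function() {
  data.frame(age_min = c(5, 10), age_max = c(10, 18),
             ref_scr = c(0.50, 0.70))
}

#' Build acute-kidney-injury scenarios
#'
#' Scenario serum creatinine is a grade multiplier times the age-band
#' reference: 1.5x (low), 2.5x (moderate), 3x (high); `"none"` (1x) is
#' available for normo-renal comparators.
#'
#' @param reference a reference table as from [reference_scr_table()].
#' @param grades subset of `c("none", "low", "moderate", "high")`.
#' @param ages optional numeric ages (years) to resolve against the table
#'   instead of taking every band; ages outside the table are an error.
#' @return data.frame of class `aki_scenarios`: age band, grade,
#'   multiplier, reference and scenario SCr.
#' @export
build_aki_scenarios <- function(reference = reference_scr_table(),
                                grades = c("low", "moderate", "high"),
                                ages = NULL) {
  mult_map <- c(none = 1, low = 1.5, moderate = 2.5, high = 3)
  grades <- match.arg(grades, names(mult_map), several.ok = TRUE)
  if (!is.null(ages)) {
    band <- vapply(ages, function(a) {
      i <- which(a >= reference$age_min & a <= reference$age_max)[1]
      if (is.na(i)) stop("age ", a, " outside the reference table")
      i
    }, 0L)
    reference <- reference[band, , drop = FALSE]
  }
  out <- merge(reference, data.frame(grade = grades,
                                     multiplier = mult_map[grades]),
               by = NULL)
  out$scenario_scr <- out$multiplier * out$ref_scr
  out <- out[order(out$age_min, out$multiplier), ]
  rownames(out) <- NULL
  class(out) <- c("aki_scenarios", "data.frame")
  out
}

#' Simulate rescue-therapy risk under kidney-injury scenarios
#'
#' For each scenario, simulates `n_sim` virtual patients with ages drawn in
#' the scenario's band (anthropometrics from the cohort generator, so BSA
#' is age-appropriate), serum creatinine fixed at the scenario value, full
#' between-subject/between-occasion/residual variability, and a standard
#' per-m^2 dose over a 4-h infusion. Concentrations are evaluated at the
#' end of infusion and 24/48/72 h later, summarized as a percentile
#' envelope with per-checkpoint probabilities of moderate and severe
#' toxicity, and flagged where the envelope crosses the protocol
#' thresholds.
#'
#' @param scenarios an `aki_scenarios` table (see [build_aki_scenarios()]).
#' @param model an `mtx_model`.
#' @param dose_per_m2 dose (g/m^2), protocol standard 12.
#' @param n_sim virtual patients per scenario.
#' @param seed optional integer seed.
#' @param envelope envelope coverage (default 95% interval).
#' @param config a [cohort_config()] for the anthropometrics.
#' @param rules a [botg_rules()] rule set.
#' @return data.frame of class `rescue_risk`: one row per scenario x
#'   checkpoint (0 = end of infusion, then 24/48/72 h post-infusion) with
#'   median and envelope concentrations, `p_moderate`, `p_severe`,
#'   `p_moderate_or_worse`, and `crosses_threshold`.
#' @export
simulate_rescue_risk <- function(scenarios, model = final_mtx_model(),
                                 dose_per_m2 = 12, n_sim = 1000, seed = NULL,
                                 envelope = 0.95, config = cohort_config(),
                                 rules = botg_rules()) {
  stopifnot(n_sim >= 1, inherits(scenarios, "data.frame"))
  if (!is.null(seed)) set.seed(seed)
  qlo <- (1 - envelope) / 2
  th <- rules$thresholds
  checkpoints <- c(0, th$checkpoint_h)   # h after end of infusion
  inf_h <- 4
  out <- list()
  for (si in seq_len(nrow(scenarios))) {
    sc <- scenarios[si, ]
    cfg <- config
    cfg$age$min <- sc$age_min
    cfg$age$max <- sc$age_max
    cfg$age$shape1 <- 1; cfg$age$shape2 <- 1   # uniform within the band
    cfg$scr$fixed <- sc$scenario_scr
    cohort <- sample_cohort(n_sim, config = cfg)
    re <- draw_random_effects(model, n_sim, 1)
    conc <- matrix(NA_real_, n_sim, length(checkpoints))
    for (i in seq_len(n_sim)) {
      ip <- individual_parameters(model, scr = sc$scenario_scr,
                                  bsa = cohort$bsa[i],
                                  eta = re$eta[i, ], kappa = re$kappa[[i]][1])
      f <- conc_2cpt(inf_h + checkpoints,
                     dose_events(0, dose_per_m2 * cohort$bsa[i] * 1000, inf_h),
                     ip$cl, ip$vc, ip$q, ip$vp)
      conc[i, ] <- as.numeric(add_residual_error(f, model$sigma_prop))
    }
    for (ci in seq_along(checkpoints)) {
      cp <- checkpoints[ci]
      x <- conc[, ci]
      if (cp == 0) {
        pm <- ps <- NA_real_
        crosses <- NA
      } else {
        i_th <- match(cp, th$checkpoint_h)
        cls <- vapply(x, classify_one, "", lower = th$target_below_mgl[i_th],
                      upper = th$moderate_upper_mgl[i_th])
        pm <- mean(cls == "moderate")
        ps <- mean(cls == "severe")
        crosses <- stats::quantile(x, 1 - qlo) >= th$target_below_mgl[i_th]
      }
      out[[length(out) + 1]] <- data.frame(
        age_min = sc$age_min, age_max = sc$age_max, grade = sc$grade,
        scenario_scr = sc$scenario_scr, checkpoint_h = cp,
        median = stats::median(x),
        lo = stats::quantile(x, qlo, names = FALSE),
        hi = stats::quantile(x, 1 - qlo, names = FALSE),
        p_moderate = pm, p_severe = ps,
        p_moderate_or_worse = if (cp == 0) NA_real_ else pm + ps,
        crosses_threshold = crosses)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  attr(res, "dose_per_m2") <- dose_per_m2
  class(res) <- c("rescue_risk", "data.frame")
  res
}
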