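#' Prediction-error validation metrics
#'
#' Per-observation relative prediction error
#' \eqn{PE_i = 100 (C_{i,pred} - C_{i,obs}) / C_{i,obs}}, summarized as
#' MPE (mean of PE), MAPE (median of PE -- the printed definition; set
#' `mape_absolute = TRUE` for the conventional median of |PE|),
#' RMSE (\eqn{\sqrt{mean(PE^2)}}), and the acceptability fractions F20 / F30
#' (percent of observations with |PE| within 20% / 30%). The clinical
#' acceptability verdict requires F20 >= 35%, F30 >= 50%, |MPE| <= 30% and
#' RMSE <= 30%.
#'
#' @param c_pred predicted concentrations (mg/L).
#' @param c_obs observed concentrations (mg/L), strictly positive.
#' @param level label: `"population"` or `"individual"`.
#' @param mape_absolute use median |PE| instead of median PE for MAPE.
#' @return object of class `validation_report` with elements `pe`, `mpe`,
#'   `mape`, `rmse`, `f20`, `f30`, `n`, `level`, per-rule `criteria` flags
#'   and the overall `acceptable` verdict.
#' @export
prediction_errors <- function(c_pred, c_obs,
                              level = c("population", "individual"),
                              mape_absolute = FALSE) {
  level <- match.arg(level)
  if (length(c_pred) != length(c_obs) || !length(c_obs)) {
    stop("c_pred and c_obs must have equal, positive length")
  }
  if (any(!is.finite(c_obs) | c_obs <= 0)) {
    stop("observed concentrations must be strictly positive")
  }
  pe <- 100 * (c_pred - c_obs) / c_obs
  mpe <- mean(pe)
  mape <- if (mape_absolute) stats::median(abs(pe)) else stats::median(pe)
  rmse <- sqrt(mean(pe^2))
  f20 <- 100 * mean(abs(pe) <= 20)
  f30 <- 100 * mean(abs(pe) <= 30)
  criteria <- c(f20 = f20 >= 35, f30 = f30 >= 50,
                mpe = abs(mpe) <= 30, rmse = rmse <= 30)
  structure(list(pe = pe, mpe = mpe, mape = mape, rmse = rmse,
                 f20 = f20, f30 = f30, n = length(pe), level = level,
                 mape_absolute = mape_absolute,
                 criteria = criteria, acceptable = all(criteria)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("%s-level predictive performance (N = %d)\n",
              x$level, x$n))
  cat(sprintf("  MPE %.2f%%, MAPE %.2f%% (F20 %.1f%%, F30 %.1f%%), RMSE %.2f%%\n",
              x$mpe, x$mape, x$f20, x$f30, x$rmse))
  cat(sprintf("  clinically acceptable: %s\n",
              if (x$acceptable) "yes" else
                paste0("no (failed: ",
                       paste(names(x$criteria)[!x$criteria], collapse = ", "),
                       ")")))
  invisible(x)
}

#' Evaluate a published model against an external dataset
#'
#' Population predictions are computed with all random effects at zero;
#' individual predictions use the MAP empirical-Bayes effects with the
#' published parameters held fixed (no re-estimation). Both prediction sets
#' are scored with [prediction_errors()].
#'
#' @param model the published `mtx_model` (parameters fixed).
#' @param data an `mtx_dataset` whose covariates cover the model's
#'   requirements.
#' @param mape_absolute passed to [prediction_errors()].
#' @return list of class `external_evaluation` with `population` and
#'   `individual` validation reports and the overall `acceptable` verdict
#'   (the population-level one).
#' @export
evaluate_external_model <- function(model, data, mape_absolute = FALSE) {
  stopifnot(inherits(model, "mtx_model"))
  pop <- predict_conc(model, data, level = "population")
  ind <- predict_conc(model, data, level = "individual")
  rep_pop <- prediction_errors(pop$PRED, pop$DV, level = "population",
                               mape_absolute = mape_absolute)
  rep_ind <- prediction_errors(ind$IPRED, ind$DV, level = "individual",
                               mape_absolute = mape_absolute)
  structure(list(population = rep_pop, individual = rep_ind,
                 acceptable = rep_pop$acceptable),
            class = "external_evaluation")
}

#' @export
print.external_evaluation <- function(x, ...) {
  print(x$population)
  print(x$individual)
  invisible(x)
}

#' Visual predictive check
#'
#' Re-simulates the dataset design (same doses, sampling times and
#' covariates; fresh between-subject, between-occasion and residual draws)
#' `n_sim` times, and summarizes simulated and observed concentrations per
#' time-after-infusion bin at the requested percentiles. Bins default to
#' windows around the nominal monitoring times (24/48/72/96 h after the end
#' of infusion, +/- `bin_halfwidth` h); observations falling outside every
#' window are collected in an `"unbinned"` row and flagged. The
#' `percentiles` presets follow the two conventions in circulation:
#' `"p5_95"` (5/50/95) and `"p10_90"` (10/50/90).
#'
#' @param data an `mtx_dataset`.
#' @param model the `mtx_model` to check.
#' @param n_sim number of simulation replicates.
#' @param bins numeric vector of nominal bin centers (h after infusion end).
#' @param bin_halfwidth half-width of each bin window (h).
#' @param percentiles numeric percentiles, or a preset name.
#' @param seed optional integer seed.
#' @return object of class `vpc_result`: per-bin observed percentiles,
#'   simulated percentile bands (median and 95% CI over replicates), the
#'   pooled simulated band, per-bin observation counts, and the fraction of
#'   observations inside the pooled outer band (`coverage`).
#' @export
vpc <- function(data, model, n_sim = 1000, bins = c(24, 48, 72, 96),
                bin_halfwidth = 3, percentiles = c(5, 50, 95), seed = NULL) {
  stopifnot(n_sim >= 1, inherits(model, "mtx_model"))
  if (is.character(percentiles)) {
    percentiles <- switch(match.arg(percentiles, c("p5_95", "p10_90")),
                          p5_95 = c(5, 50, 95), p10_90 = c(10, 50, 90))
  }
  if (!is.null(seed)) set.seed(seed)
  pre <- prepare_fit_data(data)
  ends <- cycle_infusion_end(data)
  obs <- data[data$EVID == 0, ]
  obs$tpost <- obs$TIME - ends$inf_end[match(paste(obs$ID, obs$OCC),
                                             paste(ends$ID, ends$OCC))]
  bin_of <- function(tp) {
    d <- abs(outer(tp, bins, "-"))
    j <- apply(d, 1, which.min)
    ifelse(d[cbind(seq_along(tp), j)] <= bin_halfwidth, bins[j], NA)
  }
  obs$bin <- bin_of(obs$tpost)
  n_unbinned <- sum(is.na(obs$bin))
  if (n_unbinned) {
    message(n_unbinned, " observation(s) fall outside every bin window")
  }
  # simulate: per replicate, new eta per subject, new kappa per occasion
  sims <- matrix(NA_real_, nrow(obs), n_sim)
  est_eta <- model$bsv_cl > 0 || model$bsv_vc > 0
  row_of <- split(seq_len(nrow(obs)), paste(obs$ID))
  for (s in seq_len(n_sim)) {
    re <- draw_random_effects(model, length(pre),
                              vapply(pre, `[[`, 0L, "K"))
    col <- numeric(nrow(obs))
    for (i in seq_along(pre)) {
      subj <- pre[[i]]
      mult <- occ_multipliers(model, subj$cov)
      f <- numeric(length(subj$obs_t))
      for (k in seq_len(subj$K)) {
        jj <- which(subj$obs_occ == k)
        if (!length(jj)) next
        dd <- subj$d_occ == k
        cl <- model$tvcl * mult$clm[k] * exp(re$eta[i, 1] + re$kappa[[i]][k])
        vc <- model$tvvc * mult$vcm[k] * exp(re$eta[i, 2])
        f[jj] <- conc_2cpt(subj$obs_t[jj],
                           data.frame(start = subj$d_start[dd],
                                      amt = subj$d_amt[dd],
                                      dur = subj$d_dur[dd]),
                           cl, vc, model$tvq * mult$qm[k],
                           model$tvvp * mult$vpm[k])
      }
      col[row_of[[as.character(subj$id)]]] <-
        as.numeric(add_residual_error(f, model$sigma_prop))
    }
    sims[, s] <- col
  }
  pr <- percentiles / 100
  bin_levels <- bins[bins %in% obs$bin]
  per_bin <- lapply(bin_levels, function(b) {
    ii <- which(obs$bin %in% b)
    sim_b <- sims[ii, , drop = FALSE]
    # percentile of each replicate, then median and 95% CI across replicates
    rep_q <- apply(sim_b, 2, stats::quantile, probs = pr, names = FALSE)
    if (is.null(dim(rep_q))) rep_q <- matrix(rep_q, nrow = length(pr))
    band <- t(apply(rep_q, 1, stats::quantile,
                    probs = c(0.5, 0.025, 0.975), names = FALSE))
    pooled <- stats::quantile(sim_b, probs = pr, names = FALSE)
    list(bin = b, n_obs = length(ii),
         obs_q = stats::quantile(obs$DV[ii], probs = pr, names = FALSE),
         sim_q_median = band[, 1], sim_q_lo = band[, 2], sim_q_hi = band[, 3],
         pooled_q = pooled,
         inside = obs$DV[ii] >= pooled[1] & obs$DV[ii] <= pooled[length(pr)])
  })
  inside_all <- unlist(lapply(per_bin, `[[`, "inside"))
  out <- list(bins = bin_levels, percentiles = percentiles,
              per_bin = per_bin, n_sim = n_sim,
              n_obs = nrow(obs), n_unbinned = n_unbinned,
              coverage = mean(inside_all), seed = seed)
  class(out) <- "vpc_result"
  out
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC: %d simulations, %d observations in %d bins\n",
              x$n_sim, x$n_obs, length(x$bins)))
  for (pb in x$per_bin) {
    cat(sprintf("  bin %g h (n=%d): obs [%s], sim median band [%s]\n",
                pb$bin, pb$n_obs,
                paste(signif(pb$obs_q, 3), collapse = ", "),
                paste(signif(pb$sim_q_median, 3), collapse = ", ")))
  }
  cat(sprintf("  fraction of observations inside the pooled outer band: %.3f\n",
              x$coverage))
  invisible(x)
}

#' Goodness-of-fit tables
#'
#' Observed vs population and individual predictions, plus conditional
#' weighted residuals (CWRES): per subject, the model is linearized in the
#' random effects at the MAP mode \eqn{\hat u}; with
#' \eqn{G = \partial f/\partial u|_{\hat u}}, the marginal covariance is
#' \eqn{V = G \Omega_{full} G' + diag(\sigma^2 f(\hat u)^2)} and
#' \eqn{CWRES = V^{-1/2} (y - f(\hat u) + G \hat u)}. Under the correct
#' model CWRES are approximately standard normal.
#'
#' @param fit an `mtx_fit`, or an `mtx_model` (then `data` is required).
#' @param data dataset; defaults to the fit's own data.
#' @return list of class `gof_result`: `table` (per-observation ID, OCC,
#'   TIME, DV, PRED, IPRED, IWRES, CWRES) and `summary` (mean and SD of
#'   CWRES, observed-vs-predicted regression slope).
#' @export
gof_tables <- function(fit, data = NULL) {
  if (inherits(fit, "mtx_fit")) {
    model <- fit$model
    if (is.null(data)) data <- fit$data
  } else {
    model <- fit
    if (is.null(data)) stop("data required when passing a bare model")
  }
  pre <- prepare_fit_data(data)
  est_eta <- model$bsv_cl > 0 && model$bsv_vc > 0
  est_bov <- model$bov_cl > 0
  pr <- if (est_eta) eta_prior_terms(model) else list(oinv = diag(2), ldet = 0)
  par4 <- c(model$tvcl, model$tvvc, model$tvq, model$tvvp)
  om <- omega_bsv(model)
  rows <- lapply(pre, function(subj) {
    cl <- subj_cpp_list(subj, model)
    d <- (if (est_eta) 2L else 0L) + (if (est_bov) subj$K else 0L)
    res <- subj_laplace_cpp(rep(0, d), cl, par4, pr$oinv, pr$ldet,
                            model$bov_cl^2, model$sigma_prop, est_eta, est_bov)
    u <- res$u
    f_hat <- subj_pred_cpp(u, cl, par4, pr$oinv, pr$ldet, model$bov_cl^2,
                           model$sigma_prop, est_eta, est_bov)
    f_pop <- subj_pred_cpp(rep(0, d), cl, par4, pr$oinv, pr$ldet,
                           model$bov_cl^2, model$sigma_prop, est_eta, est_bov)
    nobs <- length(subj$obs_y)
    iwres <- (subj$obs_y - f_hat) / (model$sigma_prop * pmax(f_hat, 1e-12))
    cwres <- rep(NA_real_, nobs)
    if (d > 0 && nobs > 0) {
      G <- matrix(0, nobs, d)
      h <- 1e-4 * (1 + abs(u))
      for (j in seq_len(d)) {
        up <- u; up[j] <- u[j] + h[j]
        um <- u; um[j] <- u[j] - h[j]
        G[, j] <- (subj_pred_cpp(up, cl, par4, pr$oinv, pr$ldet,
                                 model$bov_cl^2, model$sigma_prop,
                                 est_eta, est_bov) -
                   subj_pred_cpp(um, cl, par4, pr$oinv, pr$ldet,
                                 model$bov_cl^2, model$sigma_prop,
                                 est_eta, est_bov)) / (2 * h[j])
      }
      om_full <- diag(0, d)
      off <- 0
      if (est_eta) { om_full[1:2, 1:2] <- om; off <- 2 }
      if (est_bov && subj$K > 0) {
        idx <- off + seq_len(subj$K)
        om_full[cbind(idx, idx)] <- model$bov_cl^2
      }
      V <- G %*% om_full %*% t(G) +
        diag(model$sigma_prop^2 * pmax(f_hat, 1e-12)^2, nobs)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (!is.null(ch)) {
        r <- subj$obs_y - f_hat + drop(G %*% u)
        cwres <- drop(backsolve(ch, r, transpose = TRUE))
      }
    } else if (nobs > 0) {
      cwres <- iwres
    }
    data.frame(ID = subj$id, OCC = subj$occs[subj$obs_occ],
               TIME = subj$obs_t, DV = subj$obs_y,
               PRED = f_pop, IPRED = f_hat, IWRES = iwres, CWRES = cwres)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  slope <- tryCatch(unname(stats::coef(stats::lm(DV ~ PRED, data = tab))[2]),
                    error = function(e) NA_real_)
  out <- list(table = tab,
              summary = c(cwres_mean = mean(tab$CWRES, na.rm = TRUE),
                          cwres_sd = stats::sd(tab$CWRES, na.rm = TRUE),
                          obs_pred_slope = slope))
  class(out) <- "gof_result"
  out
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("GOF: %d observations; CWRES mean %.3f, SD %.3f; obs~pred slope %.3f\n",
              nrow(x$table), x$summary["cwres_mean"], x$summary["cwres_sd"],
              x$summary["obs_pred_slope"]))
  invisible(x)
}
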