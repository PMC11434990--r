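#' Dose events
#'
#' Constant-rate intravenous infusions. Times are absolute hours from the
#' start of the first infusion.
#'
#' @param start_time infusion start (h).
#' @param amount dose amount (mg); must be positive.
#' @param duration infusion length (h); protocol default 4 h.
#' @return data.frame with columns `start`, `amt`, `dur`.
#' @export
dose_events <- function(start_time, amount, duration = 4) {
  d <- data.frame(start = start_time, amt = amount, dur = duration)
  if (any(!is.finite(d$amt) | d$amt <= 0)) stop("dose amount must be positive")
  if (any(!is.finite(d$dur) | d$dur <= 0)) stop("infusion duration must be positive")
  if (any(d$start < 0)) stop("dose start times must be >= 0")
  d
}

#' Two-compartment infusion concentration (closed form)
#'
#' Central-compartment concentration for a two-compartment model with
#' first-order elimination, parametrized in clearance terms
#' (micro-constants k10 = CL/Vc, k12 = Q/Vc, k21 = Q/Vp; hybrid rate
#' constants from alpha + beta = k10 + k12 + k21, alpha beta = k10 k21).
#' Multiple infusions are handled by superposition of the biexponential
#' constant-rate solution. The degenerate alpha ~ beta case is handled by an
#' epsilon-perturbation of the root separation. `Q = 0` (or `Vp = 0`)
#' reduces exactly to the one-compartment infusion solution
#' \eqn{C = (R_0/CL)(1 - e^{-CL t / Vc})} during the infusion.
#'
#' @param times evaluation times (h, absolute); may be unsorted.
#' @param doses a data.frame as from [dose_events()].
#' @param cl,vc,q,vp individual parameters (L/h, L, L/h, L); `cl` and `vc`
#'   strictly positive, `q`, `vp` non-negative.
#' @return numeric vector of concentrations (mg/L), zero before any infusion.
#' @seealso [conc_2cpt_ode()] for the reference numerical integrator.
#' @export
conc_2cpt <- function(times, doses, cl, vc, q, vp) {
  stopifnot(is.data.frame(doses), all(c("start", "amt", "dur") %in% names(doses)))
  if (!is.finite(cl) || cl <= 0 || !is.finite(vc) || vc <= 0) {
    stop("cl and vc must be positive")
  }
  if (q < 0 || vp < 0) stop("q and vp must be non-negative")
  conc2cpt_cpp(as.numeric(times), as.numeric(doses$start),
               as.numeric(doses$amt), as.numeric(doses$dur),
               cl, vc, q, vp)
}

#' Two-compartment infusion concentration (ODE reference)
#'
#' Numerical integration of the two-compartment infusion system with
#' `deSolve::lsoda`, used as an independent reference for the closed form
#' and for mass-balance accounting.
#'
#' @inheritParams conc_2cpt
#' @param state return the full state trajectory (central amount, peripheral
#'   amount, eliminated amount) instead of concentrations.
#' @param rtol,atol integrator tolerances.
#' @return concentrations (mg/L) at `times`, or a data.frame of amounts when
#'   `state = TRUE`.
#' @export
conc_2cpt_ode <- function(times, doses, cl, vc, q, vp, state = FALSE,
                          rtol = 1e-12, atol = 1e-14) {
  k10 <- cl / vc
  k12 <- if (vc > 0) q / vc else 0
  k21 <- if (vp > 0) q / vp else 0
  deriv <- function(t, y, rate) {
    list(c(rate - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2],
           k10 * y[1]))
  }
  sol <- ode_piecewise(c(A1 = 0, A2 = 0, El = 0), times, doses, deriv,
                       rtol = rtol, atol = atol)
  if (state) {
    return(data.frame(time = times, central = sol[, 1],
                      peripheral = sol[, 2], eliminated = sol[, 3]))
  }
  sol[, 1] / vc
}

# Integrate a linear-input ODE piecewise over constant-infusion-rate
# segments, so the solver never sees a discontinuous right-hand side.
# `rhs(t, y, rate)` returns list(dy). Rows of the result correspond to
# `times` (which may be unsorted).
ode_piecewise <- function(y0, times, doses, rhs, rtol = 1e-10,
                          atol = 1e-10) {
  bounds <- sort(unique(c(0, times, doses$start, doses$start + doses$dur)))
  bounds <- bounds[bounds >= 0]
  out <- matrix(NA_real_, length(bounds), length(y0))
  y <- y0
  out[1, ] <- y
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    if (b - a < 1e-12) { out[i + 1, ] <- y; next }
    mid <- (a + b) / 2
    rate <- sum(doses$amt / doses$dur *
                  (mid >= doses$start & mid < doses$start + doses$dur))
    sol <- deSolve::lsoda(y, c(a, b),
                          function(t, y, p) rhs(t, y, rate),
                          parms = NULL, rtol = rtol, atol = atol)
    y <- sol[nrow(sol), -1]
    out[i + 1, ] <- y
  }
  out[match(times, bounds), , drop = FALSE]
}

#' Apply proportional residual error
#'
#' Observation model \eqn{y = f (1 + \sigma z)} with standard-normal `z`.
#' When `z` is not supplied, draws are taken from the current RNG stream; the
#' `"redraw"` policy re-draws any deviate that would produce a non-positive
#' observation (concentrations are physically positive and the assay reports
#' none below its quantification limit), counting the redraws in the
#' `"n_redraws"` attribute.
#'
#' @param pred model predictions f (mg/L), non-negative.
#' @param sigma_prop proportional SD (fraction).
#' @param z optional standard-normal deviates (recycled); when supplied, the
#'   value is returned as-is with no positivity policy.
#' @param policy `"redraw"` (default for simulated draws) or `"none"`.
#' @return simulated observations, same length as `pred`.
#' @export
add_residual_error <- function(pred, sigma_prop, z = NULL,
                               policy = c("redraw", "none")) {
  policy <- match.arg(policy)
  if (any(pred < 0)) stop("predictions must be non-negative")
  if (!is.null(z)) return(pred * (1 + sigma_prop * z))
  y <- pred * (1 + sigma_prop * stats::rnorm(length(pred)))
  n_redraws <- 0L
  if (policy == "redraw") {
    bad <- which(y <= 0 & pred > 0)
    while (length(bad)) {
      n_redraws <- n_redraws + length(bad)
      y[bad] <- pred[bad] * (1 + sigma_prop * stats::rnorm(length(bad)))
      bad <- bad[y[bad] <= 0]
    }
  }
  y[pred == 0] <- 0
  structure(y, n_redraws = n_redraws)
}

#' Draw subject- and occasion-level random effects
#'
#' \eqn{\eta} rows are multivariate normal with the model's BSV covariance
#' [omega_bsv()]; one \eqn{\kappa \sim N(0, \omega^2_{BOV})} is drawn per
#' occasion, all occasions sharing the single BOV variance.
#'
#' @param model an `mtx_model`.
#' @param n_subjects number of subjects.
#' @param n_occasions integer vector of occasions per subject (recycled).
#' @param seed optional integer seed for reproducibility.
#' @return list with `eta` (n x 2 matrix) and `kappa` (list of numeric
#'   vectors, one per subject).
#' @export
draw_random_effects <- function(model, n_subjects, n_occasions = 1,
                                seed = NULL) {
  stopifnot(inherits(model, "mtx_model"), n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_occasions <- rep_len(n_occasions, n_subjects)
  om <- omega_bsv(model)
  ev <- eigen(om, symmetric = TRUE)
  if (any(ev$values < -1e-12)) stop("omega_bsv is not positive semi-definite")
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  eta <- matrix(stats::rnorm(2 * n_subjects), ncol = 2) %*% rt
  colnames(eta) <- c("eta_cl", "eta_vc")
  kappa <- lapply(n_occasions, function(k) {
    stats::rnorm(k, sd = model$bov_cl)
  })
  list(eta = eta, kappa = kappa)
}
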