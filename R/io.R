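DATASET_COLS <- c("ID", "OCC", "TIME", "EVID", "AMT", "DUR", "DV")
COVARIATE_COLS <- c("SCR", "BSA", "WT", "HT", "AGE", "BUN", "AST", "ALT",
                    "HCT", "PREPOST")

#' Monitoring dataset container
#'
#' A rectangular NONMEM-style layout: one row per dosing event
#' (`EVID = 1`, with `AMT` mg and `DUR` h, or `RATE` mg/h) or observation
#' (`EVID = 0`, with `DV` mg/L), columns `ID`, `OCC` (treatment cycle),
#' `TIME` (decimal hours from the first infusion start), and covariate
#' columns (`SCR`, `BSA`, optionally `WT`, `HT`, `AGE`, `SEX`, ...).
#'
#' @param x a data.frame with the columns above (a `RATE` column is
#'   converted to `DUR = AMT/RATE`).
#' @return the validated `mtx_dataset`.
#' @export
as_mtx_dataset <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x)
  if (!"OCC" %in% names(x)) x$OCC <- 1L
  if (!"DUR" %in% names(x) && "RATE" %in% names(x)) {
    x$DUR <- ifelse(x$EVID == 1, x$AMT / x$RATE, NA_real_)
  }
  missing_cols <- setdiff(DATASET_COLS, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  x$ID <- as.integer(x$ID)
  x$OCC <- as.integer(x$OCC)
  x$EVID <- as.integer(x$EVID)
  for (cc in c("TIME", "AMT", "DUR", "DV")) x[[cc]] <- as.numeric(x[[cc]])
  x <- x[order(x$ID, x$TIME, -x$EVID), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("mtx_dataset", "data.frame")
  validate_mtx_dataset(x)
  x
}

#' Validate a monitoring dataset
#'
#' Checks the structural invariants: every (ID, OCC) cycle has at least one
#' dose row; observation `DV` strictly positive; dose `AMT` and `DUR`
#' positive; `TIME` non-negative. Violations are reported with the
#' offending row numbers.
#'
#' @param x an `mtx_dataset`.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_mtx_dataset <- function(x) {
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      stop(what, " (row ", paste(utils::head(which(cond), 10), collapse = ", "),
           ")", call. = FALSE)
    }
  }
  obs <- x$EVID == 0
  dose <- x$EVID == 1
  bad_row(!x$EVID %in% c(0L, 1L), "EVID must be 0 or 1")
  bad_row(is.na(x$TIME) | x$TIME < 0, "TIME must be >= 0")
  bad_row(obs & (is.na(x$DV) | x$DV <= 0),
          "observation DV must be positive (no below-LLOQ handling)")
  bad_row(dose & (is.na(x$AMT) | x$AMT <= 0), "dose AMT must be positive")
  bad_row(dose & (is.na(x$DUR) | x$DUR <= 0), "dose DUR must be positive")
  cyc <- unique(x[, c("ID", "OCC")])
  has_dose <- unique(x[dose, c("ID", "OCC")])
  orphan <- !paste(cyc$ID, cyc$OCC) %in% paste(has_dose$ID, has_dose$OCC)
  if (any(orphan)) {
    stop("cycle(s) without a dose row: ",
         paste(paste0("ID ", cyc$ID[orphan], "/OCC ", cyc$OCC[orphan]),
               collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a monitoring dataset from CSV
#'
#' Reads the NONMEM-style CSV dialect (missing cells empty or `"."`),
#' validates it, and by default applies the study inclusion filters
#' (see [apply_inclusion_filters()]), logging row counts and exclusions.
#'
#' @param path CSV file path.
#' @param apply_filters apply the inclusion rules after validation.
#' @param quiet suppress the row-count message.
#' @return an `mtx_dataset`; when filtered, the exclusion report is attached
#'   as attribute `"exclusions"`.
#' @export
read_mtx_dataset <- function(path, apply_filters = TRUE, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, na.strings = c("", ".", "NA"),
                         stringsAsFactors = FALSE)
  d <- as_mtx_dataset(raw)
  if (!quiet) {
    message(sprintf("read %d rows (%d doses, %d observations) from %s",
                    nrow(d), sum(d$EVID == 1), sum(d$EVID == 0), path))
  }
  if (apply_filters) d <- apply_inclusion_filters(d, quiet = quiet)
  d
}

#' Write a monitoring dataset to CSV
#'
#' Missing cells are written as `"."` (NONMEM dialect), so that
#' `read_mtx_dataset(write_mtx_dataset(x))` round-trips.
#'
#' @param x an `mtx_dataset`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_mtx_dataset <- function(x, path) {
  stopifnot(inherits(x, "mtx_dataset"))
  utils::write.csv(x, path, row.names = FALSE, na = ".")
  invisible(path)
}

cycle_infusion_end <- function(x) {
  dose <- x[x$EVID == 1, c("ID", "OCC", "TIME", "DUR")]
  ends <- stats::aggregate(TIME + DUR ~ ID + OCC, data = dose, FUN = max)
  names(ends)[3] <- "inf_end"
  ends
}

#' Apply the study inclusion filters
#'
#' Two rules: observations later than `max_post_h` hours after the end of
#' their cycle's infusion are removed (beyond that window patients may be
#' selected for dialysis, which would bias clearance), and cycles left with
#' fewer than `min_obs` observations are removed entirely. The filters are
#' idempotent.
#'
#' @param x an `mtx_dataset`.
#' @param max_post_h latest allowed observation time after infusion end (h).
#' @param min_obs minimum observations per cycle.
#' @param quiet suppress the exclusion log message.
#' @return the filtered `mtx_dataset` with attribute `"exclusions"`, a list
#'   with counts `obs_beyond_window` and `cycles_below_min_obs`.
#' @export
apply_inclusion_filters <- function(x, max_post_h = 96, min_obs = 2,
                                    quiet = FALSE) {
  stopifnot(inherits(x, "mtx_dataset"))
  ends <- cycle_infusion_end(x)
  m <- merge(x, ends, by = c("ID", "OCC"), sort = FALSE)
  m <- m[order(m$ID, m$TIME, -m$EVID), ]
  late <- m$EVID == 0 & (m$TIME - m$inf_end) > max_post_h + 1e-9
  n_late <- sum(late)
  m <- m[!late, ]
  nobs <- stats::aggregate(EVID == 0 ~ ID + OCC, data = m, FUN = sum)
  names(nobs)[3] <- "n_obs"
  drop_cyc <- nobs[nobs$n_obs < min_obs, c("ID", "OCC"), drop = FALSE]
  n_drop <- nrow(drop_cyc)
  if (n_drop) {
    keep <- !paste(m$ID, m$OCC) %in% paste(drop_cyc$ID, drop_cyc$OCC)
    m <- m[keep, ]
  }
  m$inf_end <- NULL
  rownames(m) <- NULL
  class(m) <- c("mtx_dataset", "data.frame")
  if (!quiet && (n_late || n_drop)) {
    message(sprintf(paste0("inclusion filters: removed %d observation(s) ",
                           "beyond %g h post-infusion and %d cycle(s) with ",
                           "fewer than %d observations"),
                    n_late, max_post_h, n_drop, min_obs))
  }
  if (!nrow(m) || !sum(m$EVID == 0)) {
    warning("no observations remain after inclusion filtering")
  }
  attr(m, "exclusions") <- list(obs_beyond_window = n_late,
                                cycles_below_min_obs = n_drop)
  m
}

#' Impute missing covariate values
#'
#' Missing continuous covariates are replaced, within each patient, by the
#' value at the nearest record in time; ties are broken toward the earlier
#' record.
#'
#' @param x an `mtx_dataset`.
#' @param covariates covariate columns to fill; defaults to the standard
#'   continuous covariates present in `x`.
#' @param quiet suppress the imputation-count message.
#' @return the dataset with missing values filled; the per-covariate counts
#'   are attached as attribute `"imputed"`.
#' @export
impute_missing_covariates <- function(x, covariates = NULL, quiet = FALSE) {
  stopifnot(inherits(x, "mtx_dataset"))
  if (is.null(covariates)) {
    covariates <- intersect(COVARIATE_COLS, names(x))
  }
  counts <- stats::setNames(integer(length(covariates)), covariates)
  for (cc in covariates) {
    for (id in unique(x$ID)) {
      ii <- which(x$ID == id)
      v <- x[[cc]][ii]
      miss <- is.na(v)
      if (!any(miss)) next
      if (all(miss)) {
        stop("covariate '", cc, "' entirely missing for patient ", id)
      }
      tt <- x$TIME[ii]
      src <- which(!miss)
      for (j in which(miss)) {
        dt <- abs(tt[src] - tt[j])
        best <- src[order(dt, tt[src])][1]  # tie -> earlier record
        v[j] <- v[best]
      }
      x[[cc]][ii] <- v
      counts[cc] <- counts[cc] + sum(miss)
    }
  }
  if (!quiet && sum(counts)) {
    message("imputed missing covariates: ",
            paste(sprintf("%s=%d", names(counts)[counts > 0],
                          counts[counts > 0]), collapse = ", "))
  }
  attr(x, "imputed") <- as.list(counts)
  x
}
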