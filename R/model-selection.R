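## Cohort-level selection of the calibration-error model by delta-BIC.

#' Enumerate candidate calibration-error models
#'
#' @param families Function families considered for both a(t) and b(t);
#'   the default full set gives the 25 candidates.
#' @return Named list of [cal_spec()] objects, named `"a:b"`.
#' @export
candidate_specs <- function(families = CAL_FAMILIES) {
  out <- list()
  for (a in families) for (b in families) {
    s <- cal_spec(a, b)
    out[[cal_spec_id(s)]] <- s
  }
  out
}

#' Fit every candidate calibration model to every sensor
#'
#' For each sensor's matched pairs and each candidate spec, runs the first
#' identification step, whitens the residuals with an AR(2) inverse filter
#' and computes the BIC. Per-cell convergence failures are recorded, not
#' fatal.
#'
#' @param cohort List of [match_cgm()] results, one per sensor.
#' @param candidates Named list of [cal_spec()] (default: all 25).
#' @param sensor_ids Optional sensor labels.
#' @return An object of class `bic_table`: list with `bic` (sensor x
#'   candidate matrix), `converged` (logical matrix) and `candidates`.
#' @export
evaluate_candidates <- function(cohort, candidates = candidate_specs(),
                                sensor_ids = NULL) {
  if (length(cohort) == 0L) stopf("cohort is empty")
  if (is.null(sensor_ids)) sensor_ids <- seq_along(cohort)
  bic <- matrix(NA_real_, length(cohort), length(candidates),
                dimnames = list(sensor_ids, names(candidates)))
  conv <- matrix(FALSE, length(cohort), length(candidates),
                 dimnames = dimnames(bic))
  for (i in seq_along(cohort)) {
    for (j in seq_along(candidates)) {
      cell <- tryCatch({
        s1 <- suppressWarnings(fit_step1(cohort[[i]], candidates[[j]]))
        wh <- whiten_residuals(s1$residuals)
        list(bic = as.numeric(compute_bic(wh$rss, wh$n,
                                          n_cal_params(candidates[[j]]))),
             converged = s1$converged)
      }, error = function(e) list(bic = NA_real_, converged = FALSE))
      bic[i, j] <- cell$bic
      conv[i, j] <- cell$converged
    }
  }
  structure(list(bic = bic, converged = conv, candidates = candidates),
            class = "bic_table")
}

#' @export
print.bic_table <- function(x, ...) {
  cat(sprintf("<bic_table> %d sensor(s) x %d candidate(s), %d non-converged cell(s)\n",
              nrow(x$bic), ncol(x$bic), sum(!x$converged)))
  invisible(x)
}

#' Per-candidate distributions of BIC differences against a reference model
#'
#' @param table A [evaluate_candidates()] result.
#' @param reference Candidate id (e.g. `"poly0:poly0"`).
#' @return Matrix of `BIC(candidate) - BIC(reference)` per sensor and
#'   candidate.
#' @export
delta_bic <- function(table, reference = "poly0:poly0") {
  if (!reference %in% colnames(table$bic))
    stopf("reference candidate %s absent from the table", reference)
  sweep(table$bic, 1L, table$bic[, reference])
}

#' Select the optimal calibration-error model from a cohort BIC table
#'
#' Ranks candidates by the median (across sensors) of their BIC difference
#' from the time-invariant reference model. Among candidates whose medians
#' lie within `margin` BIC units of the best, the simplest one (fewest
#' calibration parameters; ties broken toward lower polynomial order of
#' a(t)) is selected.
#'
#' @param table A [evaluate_candidates()] result.
#' @param reference Reference candidate id (default `"poly0:poly0"`).
#' @param margin Equivalence margin in BIC units (default 2).
#' @return List with `selected` (candidate id), `median_delta_bic` (named,
#'   sorted) and `runners_up` (ids within the margin, in rank order).
#' @export
select_optimal <- function(table, reference = "poly0:poly0", margin = 2) {
  d <- delta_bic(table, reference)
  med <- apply(d, 2L, stats::median, na.rm = TRUE)
  med <- sort(med)
  best <- med[1L]
  tied <- names(med)[med <= best + margin]
  np <- vapply(tied, function(id) n_cal_params(table$candidates[[id]]),
               integer(1L))
  a_ord <- vapply(tied, function(id) {
    fam <- table$candidates[[id]]$a_family
    if (fam == "exp") 9L else as.integer(substring(fam, 5L))
  }, integer(1L))
  sel <- tied[order(np, a_ord)][1L]
  list(selected = sel, median_delta_bic = med,
       runners_up = setdiff(tied, sel))
}
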