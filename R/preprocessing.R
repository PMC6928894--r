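## Trace-selection and sample-exclusion rules applied to a multi-sensor
## dataset before identification.

#' One sensor's raw record
#'
#' @param sensor_id Identifier.
#' @param cgm A CGM `glucose_trace`.
#' @param reference A [reference_samples()] object (same insertion-time
#'   origin as the CGM trace).
#' @param session_days Sorted integer days (1-based) of the clinical
#'   sessions.
#' @return An object of class `sensor_record`.
#' @export
sensor_record <- function(sensor_id, cgm, reference, session_days) {
  session_days <- as.integer(session_days)
  if (is.unsorted(session_days)) stopf("session_days must be sorted")
  structure(list(sensor_id = sensor_id, cgm = cgm, reference = reference,
                 session_days = session_days),
            class = "sensor_record")
}

#' Remove display-saturated CGM readings
#'
#' Drops samples at or beyond the device display limits (<= 40 or >= 400
#' mg/dL) and recomputes segment ids: a retained sample starts a new segment
#' whenever its predecessor in the original trace was removed or belonged to
#' a different segment.
#'
#' @param cgm A CGM `glucose_trace`.
#' @return A `glucose_trace` without saturated samples; attribute
#'   `n_removed` counts dropped samples. An empty trace (all saturated)
#'   carries attribute `all_saturated = TRUE`.
#' @export
remove_saturated <- function(cgm) {
  keep <- which(cgm$glucose_mg_dl > 40 & cgm$glucose_mg_dl < 400)
  if (length(keep) == 0L) {
    out <- glucose_trace(numeric(), numeric(), integer(),
                         period = attr(cgm, "period"))
    attr(out, "n_removed") <- nrow(cgm)
    attr(out, "all_saturated") <- TRUE
    return(out)
  }
  new_seg <- run_ids(c(TRUE, diff(keep) != 1L |
                         diff(cgm$segment_id[keep]) != 0L))
  out <- glucose_trace(cgm$time_min[keep], cgm$glucose_mg_dl[keep],
                       new_seg, period = attr(cgm, "period"))
  attr(out, "n_removed") <- nrow(cgm) - length(keep)
  out
}

day10_window <- function(day) c((day - 1) * 1440, day * 1440)

#' Apply the cohort trace-selection rules
#'
#' A record is retained when (i) its CGM trace spans at least
#' `min_duration_h` hours, (ii) its last clinical session is on day
#' `required_last_day`, and (iii) at least `min_last_day_refs` reference
#' samples fall in that day (a sample belongs to day d iff its time lies in
#' `[(d-1)*1440, d*1440)` minutes).
#'
#' @param records List of [sensor_record()] objects.
#' @param min_duration_h Minimum CGM span in hours (default 12).
#' @param required_last_day Required day of the final session (default 10).
#' @param min_last_day_refs Minimum number of reference samples in the final
#'   day (default 8).
#' @return A list with `retained` (sensor records) and `excluded`, a
#'   data.frame of `sensor_id` and comma-joined `reason` strings.
#' @export
select_traces <- function(records, min_duration_h = 12,
                          required_last_day = 10, min_last_day_refs = 8) {
  reasons <- lapply(records, function(r) {
    out <- character()
    span_h <- if (nrow(r$cgm) > 1L)
      (max(r$cgm$time_min) - min(r$cgm$time_min)) / 60 else 0
    if (span_h < min_duration_h) out <- c(out, "insufficient data")
    if (length(r$session_days) == 0L ||
        max(r$session_days) != required_last_day)
      out <- c(out, sprintf("last session not day %d", required_last_day))
    win <- day10_window(required_last_day)
    n10 <- sum(r$reference$times >= win[1L] & r$reference$times < win[2L])
    if (n10 < min_last_day_refs)
      out <- c(out, sprintf("fewer than %d day-%d reference samples",
                            min_last_day_refs, required_last_day))
    out
  })
  ok <- lengths(reasons) == 0L
  excluded <- data.frame(
    sensor_id = vapply(records[!ok], function(r) as.character(r$sensor_id),
                       character(1L)),
    reason = vapply(reasons[!ok], paste, character(1L), collapse = "; "),
    stringsAsFactors = FALSE)
  list(retained = records[ok], excluded = excluded)
}

#' Flag likely reference-sample spikes (automated stand-in)
#'
#' The published preprocessing removed reference outliers by visual
#' inspection, a manual step. This automated stand-in flags a sample when it
#' deviates from the median of its two neighbours by more than
#' `k * cv * value`. It is OFF by default throughout the package and is not
#' part of the published procedure.
#'
#' @param samples A [reference_samples()].
#' @param k Deviation multiple (default 4).
#' @return Logical vector, `TRUE` for flagged samples (first and last are
#'   never flagged).
#' @export
flag_reference_outliers <- function(samples, k = 4) {
  v <- samples$values
  n <- length(v)
  flag <- rep.int(FALSE, n)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      med <- stats::median(c(v[i - 1L], v[i + 1L]))
      flag[i] <- abs(v[i] - med) > k * samples$cv * v[i]
    }
  }
  flag
}
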