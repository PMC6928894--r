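#' Timestamped glucose series
#'
#' A `glucose_trace` stores a glucose time series: times in minutes since
#' sensor insertion, glucose values in mg/dL, and an integer segment label
#' grouping contiguous runs of samples (for example one clinical session).
#' Depending on context a trace holds blood glucose (BG), interstitial
#' glucose (IG), the calibrated noiseless sensor signal, or CGM readings.
#'
#' @param times Numeric, minutes since insertion; non-negative, strictly
#'   increasing.
#' @param values Numeric glucose in mg/dL; finite and positive.
#' @param segment_ids Integer labels of contiguous runs; defaults to a single
#'   segment.
#' @param period Declared within-segment sampling period in minutes, or `NA`
#'   for irregular series. When given, gaps between consecutive samples of a
#'   segment must equal it to within 1e-9.
#' @param positive Require values > 0 (default). Intermediate model signals
#'   (e.g. a calibrated trace under extreme gain drift, before display
#'   clipping) may legitimately cross zero and are built with
#'   `positive = FALSE`.
#' @return An object of class `glucose_trace` (a data.frame with columns
#'   `time_min`, `glucose_mg_dl`, `segment_id` and a `period` attribute).
#' @export
glucose_trace <- function(times, values, segment_ids = NULL, period = NA_real_,
                          positive = TRUE) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stopf("times and values must have equal length")
  if (is.null(segment_ids)) segment_ids <- rep.int(1L, length(times))
  segment_ids <- as.integer(segment_ids)
  out <- data.frame(time_min = times, glucose_mg_dl = values,
                    segment_id = segment_ids)
  attr(out, "period") <- period
  class(out) <- c("glucose_trace", "data.frame")
  validate_glucose_trace(out, positive = positive)
  out
}

validate_glucose_trace <- function(x, positive = TRUE) {
  t <- x$time_min; v <- x$glucose_mg_dl
  if (length(t) == 0L) return(invisible(x))
  if (anyNA(t) || any(!is.finite(t))) stopf("times must be finite")
  if (any(t < 0)) stopf("times must be non-negative")
  if (any(diff(t) <= 0)) stopf("times must be strictly increasing")
  if (anyNA(v) || any(!is.finite(v)))
    stopf("glucose values must be finite")
  if (positive && any(v <= 0))
    stopf("glucose values must be > 0")
  p <- attr(x, "period")
  if (!is.na(p)) {
    for (s in split(t, x$segment_id)) {
      if (length(s) > 1L && any(abs(diff(s) - p) > 1e-9))
        stopf("within-segment gaps must equal the declared period (%g min)", p)
    }
  }
  invisible(x)
}

trace_segments <- function(x) split(seq_len(nrow(x)), x$segment_id)

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("<glucose_trace> %d samples, %d segment(s), period %s min, %.0f-%.0f min\n",
              nrow(x), length(unique(x$segment_id)),
              format(attr(x, "period")),
              if (nrow(x)) min(x$time_min) else NA,
              if (nrow(x)) max(x$time_min) else NA))
  invisible(x)
}

#' Sparse reference (YSI-style) glucose samples
#'
#' Laboratory reference blood-glucose samples taken every ~15 min inside
#' clinical sessions, with an assumed multiplicative measurement error
#' (white noise, coefficient of variation `cv`).
#'
#' @param times Minutes since insertion, strictly increasing.
#' @param values Glucose in mg/dL, positive.
#' @param cv Assumed coefficient of variation of the reference assay
#'   (default 0.02, i.e. 2%); must lie in (0, 0.5).
#' @return An object of class `reference_samples`.
#' @export
reference_samples <- function(times, values, cv = 0.02) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stopf("times and values must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stopf("times must be strictly increasing")
  if (any(values <= 0) || anyNA(values)) stopf("values must be > 0")
  if (!(cv > 0 && cv < 0.5)) stopf("cv must lie in (0, 0.5)")
  structure(list(times = times, values = values, cv = cv),
            class = "reference_samples")
}

#' @export
print.reference_samples <- function(x, ...) {
  cat(sprintf("<reference_samples> %d samples, cv = %.3f\n",
              length(x$times), x$cv))
  invisible(x)
}

#' Read / write a glucose trace as CSV
#'
#' CSV dialect: comma separated, '.' decimal, UTF-8, mandatory header with
#' columns `time_min`, `glucose_mg_dl`, `segment_id`.
#'
#' @param path File path.
#' @param period Declared sampling period passed to [glucose_trace()].
#' @return `read_trace_csv` returns a `glucose_trace`.
#' @export
read_trace_csv <- function(path, period = NA_real_) {
  df <- utils::read.csv(path)
  need <- c("time_min", "glucose_mg_dl", "segment_id")
  if (!all(need %in% names(df)))
    stopf("trace CSV must have columns %s", paste(need, collapse = ", "))
  glucose_trace(df$time_min, df$glucose_mg_dl, df$segment_id, period = period)
}

#' @rdname read_trace_csv
#' @param x A `glucose_trace`.
#' @export
write_trace_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("time_min", "glucose_mg_dl", "segment_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trace_csv
#' @param cv Assay coefficient of variation for the returned object.
#' @export
read_reference_csv <- function(path, cv = 0.02) {
  df <- utils::read.csv(path)
  need <- c("time_min", "glucose_mg_dl")
  if (!all(need %in% names(df)))
    stopf("reference CSV must have columns %s", paste(need, collapse = ", "))
  reference_samples(df$time_min, df$glucose_mg_dl, cv = cv)
}

#' @rdname read_trace_csv
#' @export
write_reference_csv <- function(x, path) {
  utils::write.csv(data.frame(time_min = x$times, glucose_mg_dl = x$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
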