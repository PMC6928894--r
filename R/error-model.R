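## Generative sensor-error model: BG-to-IG kinetics (block A), time-varying
## calibration error (block B), autoregressive measurement noise (block C).

#' Kinetics parameters: the BG-to-IG diffusion time constant
#'
#' Plasma-to-interstitium glucose transport behaves, under the steady-state
#' balance assumption, as a first-order linear system with impulse response
#' h(t) = (1/tau) exp(-t/tau). `tau = 0` means no delay (identity).
#'
#' @param tau Diffusion time constant in minutes, `>= 0`, finite.
#' @return An object of class `kinetics_params`.
#' @export
kinetics_params <- function(tau) {
  tau <- as.numeric(tau)
  if (length(tau) != 1L || !is.finite(tau) || tau < 0)
    stopf("tau must be a single finite value >= 0 (minutes)")
  structure(list(tau = tau), class = "kinetics_params")
}

#' Convolve blood glucose with first-order diffusion kinetics
#'
#' Computes interstitial glucose IG(t) = h(t) * BG(t), h(t) = (1/tau)
#' exp(-t/tau), discretised per segment by the exact zero-order-hold
#' recursion `IG[k] = phi * IG[k-1] + (1 - phi) * BG[k]` with
#' `phi = exp(-dt/tau)`. The recursion is exact when the input is held at
#' `BG[k]` over `(t[k-1], t[k]]`. The first sample of each segment starts at
#' steady state, `IG = BG`. `tau = 0` returns the input unchanged.
#'
#' @param bg A [glucose_trace()] sampled on a uniform grid within each
#'   segment (1-min grid recommended).
#' @param kinetics A [kinetics_params()] or a bare tau in minutes.
#' @return A `glucose_trace` of IG values on the same time grid.
#' @export
bg_to_ig <- function(bg, kinetics) {
  if (!inherits(kinetics, "kinetics_params"))
    kinetics <- kinetics_params(kinetics)
  tau <- kinetics$tau
  out <- bg$glucose_mg_dl
  if (tau > 0) {
    for (idx in trace_segments(bg)) {
      t <- bg$time_min[idx]
      if (length(idx) > 1L) {
        dt <- diff(t)
        if (any(abs(dt - dt[1L]) > 1e-9))
          stopf("bg_to_ig requires a uniform time grid within each segment")
        phi <- exp(-dt[1L] / tau)
        x <- bg$glucose_mg_dl[idx]
        # IG[k] = phi IG[k-1] + (1-phi) BG[k]; steady-state start IG[1]=BG[1]
        y <- stats::filter((1 - phi) * x, phi, method = "recursive",
                           init = x[1L])
        out[idx] <- as.numeric(y)
        out[idx[1L]] <- x[1L]
      }
    }
  }
  glucose_trace(bg$time_min, out, bg$segment_id, period = attr(bg, "period"))
}

## ---- calibration error ----------------------------------------------------

CAL_FAMILIES <- c("poly0", "poly1", "poly2", "poly3", "exp")

#' Calibration-error model specification
#'
#' One of the 25 candidate calibration-error models: the gain a(t) and the
#' offset b(t) are each drawn from the families poly0..poly3 (polynomials of
#' order 0-3 in time since insertion, expressed in days) or `exp` (a
#' three-parameter exponential: initial value, final value, time constant in
#' days).
#'
#' @param a_family,b_family One of `"poly0"`, `"poly1"`, `"poly2"`,
#'   `"poly3"`, `"exp"`.
#' @return An object of class `cal_spec`.
#' @export
cal_spec <- function(a_family = "poly0", b_family = "poly0") {
  a_family <- match.arg(a_family, CAL_FAMILIES)
  b_family <- match.arg(b_family, CAL_FAMILIES)
  structure(list(a_family = a_family, b_family = b_family),
            class = "cal_spec")
}

#' @export
print.cal_spec <- function(x, ...) {
  cat(sprintf("<cal_spec> (%s, %s), %d calibration parameters\n",
              x$a_family, x$b_family, n_cal_params(x)))
  invisible(x)
}

family_n_params <- function(family) {
  if (family == "exp") 3L else as.integer(substring(family, 5L)) + 1L
}

#' Number of free calibration coefficients of a candidate model
#'
#' `polym` has m+1 coefficients; `exp` has 3.
#' @param spec A [cal_spec()].
#' @return Integer count N_p over both a(t) and b(t).
#' @export
n_cal_params <- function(spec) {
  family_n_params(spec$a_family) + family_n_params(spec$b_family)
}

cal_spec_id <- function(spec) paste(spec$a_family, spec$b_family, sep = ":")

cal_spec_from_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1L]]
  cal_spec(parts[1L], parts[2L])
}

#' Calibration-error coefficients
#'
#' Coefficients for the gain a(t) and offset b(t) of the chosen
#' [cal_spec()]. For `polym` the k-th coefficient multiplies t^k with t in
#' DAYS since insertion (so coefficients carry units days^-k). For `exp`
#' the three coefficients are (initial value, final value, time constant in
#' days), evaluated as `p1 + (p0 - p1) * exp(-t_days / p2)`.
#'
#' @param spec A [cal_spec()].
#' @param a_coeffs,b_coeffs Numeric coefficient vectors matching the
#'   family's parameter count.
#' @return An object of class `cal_params`.
#' @export
cal_params <- function(spec, a_coeffs, b_coeffs) {
  check_coeffs <- function(coeffs, family, what) {
    if (length(coeffs) != family_n_params(family))
      stopf("%s needs %d coefficients for family %s, got %d",
            what, family_n_params(family), family, length(coeffs))
    if (family == "exp" && coeffs[3L] <= 0)
      stopf("%s exponential time constant must be > 0 days", what)
  }
  check_coeffs(a_coeffs, spec$a_family, "a(t)")
  check_coeffs(b_coeffs, spec$b_family, "b(t)")
  structure(list(spec = spec, a_coeffs = as.numeric(a_coeffs),
                 b_coeffs = as.numeric(b_coeffs)),
            class = "cal_params")
}

eval_cal_family <- function(family, coeffs, t_days) {
  if (family == "exp") {
    coeffs[2L] + (coeffs[1L] - coeffs[2L]) * exp(-t_days / coeffs[3L])
  } else {
    # Horner evaluation of sum_k p_k t^k
    out <- rep.int(coeffs[length(coeffs)], length(t_days))
    if (length(coeffs) > 1L)
      for (k in rev(seq_len(length(coeffs) - 1L)))
        out <- out * t_days + coeffs[k]
    out
  }
}

#' Evaluate the calibration gain and offset over time
#'
#' @param cal A [cal_params()].
#' @param times Minutes since insertion (>= 0). The polynomial/exponential
#'   argument is time in days, `times / 1440`.
#' @return A list with numeric vectors `a` (gain) and `b` (offset, mg/dL).
#' @export
eval_calibration <- function(cal, times) {
  if (any(times < 0)) stopf("times must be >= 0")
  t_days <- times / 1440
  list(a = eval_cal_family(cal$spec$a_family, cal$a_coeffs, t_days),
       b = eval_cal_family(cal$spec$b_family, cal$b_coeffs, t_days))
}

#' Apply the calibration error to an interstitial glucose trace
#'
#' Returns the noiseless sensor signal IGs(t) = a(t) IG(t) + b(t).
#'
#' @param ig A `glucose_trace` of interstitial glucose.
#' @param cal A [cal_params()].
#' @return A `glucose_trace` of IGs values.
#' @export
apply_calibration <- function(ig, cal) {
  ab <- eval_calibration(cal, ig$time_min)
  glucose_trace(ig$time_min, ab$a * ig$glucose_mg_dl + ab$b,
                ig$segment_id, period = attr(ig, "period"), positive = FALSE)
}

## ---- AR measurement noise --------------------------------------------------

#' Autoregressive measurement-noise parameters
#'
#' The residual sensor noise v(t) follows an AR(q) process at the CGM
#' sampling period T: `v(t) = sum_k alpha_k v(t - kT) + w(t)` with w(t)
#' zero-mean Gaussian white noise of standard deviation `sigma`.
#' Stationarity requires all roots of `A(z) = 1 - alpha1 z - ... - alphaq
#' z^q` to lie strictly inside the unit circle (equivalently: the process
#' poles inside the unit circle in the usual z^-1 convention).
#'
#' @param alpha Numeric AR coefficients (may be empty for pure white noise).
#' @param sigma Driving white-noise SD in mg/dL, > 0 (0 allowed for a
#'   noiseless sensor).
#' @param period Sampling period T in minutes (default 5).
#' @return An object of class `ar_noise_params`.
#' @export
ar_noise_params <- function(alpha = numeric(), sigma, period = 5) {
  alpha <- as.numeric(alpha)
  if (!ar_is_stationary(alpha))
    stopf("AR coefficients are not stationary: characteristic roots must lie strictly inside the unit circle")
  if (sigma < 0) stopf("sigma must be >= 0")
  structure(list(alpha = alpha, sigma = as.numeric(sigma),
                 period = as.numeric(period)),
            class = "ar_noise_params")
}

#' Check stationarity of AR coefficients
#'
#' @param alpha AR coefficients alpha_1..alpha_q.
#' @param margin Required distance of every characteristic root from the
#'   unit circle (default 0: strict interior).
#' @return `TRUE` if all roots of the process characteristic polynomial lie
#'   strictly inside the unit circle (with the given margin).
#' @export
ar_is_stationary <- function(alpha, margin = 0) {
  if (length(alpha) == 0L) return(TRUE)
  if (anyNA(alpha) || any(!is.finite(alpha))) return(FALSE)
  # roots of z^q - alpha1 z^(q-1) - ... - alphaq; the 1e-6 slack absorbs
  # polyroot's numerical error so exact unit roots are classified unstable
  r <- polyroot(c(-rev(alpha), 1))
  all(Mod(r) < 1 - margin - 1e-6)
}

#' Simulate stationary AR noise
#'
#' Draws `n` samples of the AR(q) noise process after discarding `burn_in`
#' initial samples so the output is approximately stationary.
#'
#' @param noise An [ar_noise_params()].
#' @param n Number of samples to return.
#' @param seed Integer seed (the RNG state of the caller is untouched).
#' @param burn_in Samples discarded before recording (default 500).
#' @return Numeric vector of length `n` (mg/dL).
#' @export
simulate_ar_noise <- function(noise, n, seed = NULL, burn_in = 500L) {
  if (n < 1) stopf("n must be >= 1")
  if (!ar_is_stationary(noise$alpha))
    stopf("cannot simulate a non-stationary AR process")
  w <- with_local_seed(seed, stats::rnorm(n + burn_in, 0, noise$sigma))
  v <- if (length(noise$alpha)) {
    as.numeric(stats::filter(w, noise$alpha, method = "recursive"))
  } else w
  v[(burn_in + 1L):(burn_in + n)]
}

## ---- full parameter set + forward simulation -------------------------------

#' Full sensor-error parameter set
#'
#' Bundles the kinetic time constant, the calibration-error model and
#' coefficients, and the AR noise parameters of one sensor.
#'
#' @param kinetics A [kinetics_params()].
#' @param cal A [cal_params()] (carries its [cal_spec()]).
#' @param noise An [ar_noise_params()].
#' @return An object of class `sensor_error_params`.
#' @export
sensor_error_params <- function(kinetics, cal, noise) {
  structure(list(kinetics = kinetics, cal = cal, noise = noise),
            class = "sensor_error_params")
}

#' @export
print.sensor_error_params <- function(x, ...) {
  cat(sprintf("<sensor_error_params> tau = %.2f min, cal (%s, %s), AR(%d), sigma = %.2f mg/dL\n",
              x$kinetics$tau, x$cal$spec$a_family, x$cal$spec$b_family,
              length(x$noise$alpha), x$noise$sigma))
  invisible(x)
}

#' Simulate a CGM trace from a blood-glucose profile
#'
#' Composes the three error blocks: BG-to-IG kinetics, calibration error,
#' AR measurement noise. The 1-min BG profile is convolved with the kinetic
#' impulse response, distorted by a(t), b(t), downsampled to the CGM period,
#' and corrupted with AR noise. Output values are clipped to the device
#' display range [40, 400] mg/dL; clipped samples are flagged in the
#' `saturated` attribute, mirroring the saturation readings a real device
#' would report.
#'
#' @param bg BG `glucose_trace` on a uniform 1-min grid.
#' @param params A [sensor_error_params()].
#' @param cgm_period CGM sampling period in minutes (default 5); must be a
#'   multiple of the BG grid step.
#' @param seed Integer seed for the noise draw.
#' @return A `glucose_trace` of CGM readings at the CGM period, with a
#'   logical attribute `saturated` marking clipped samples.
#' @export
simulate_cgm <- function(bg, params, cgm_period = 5, seed = NULL) {
  dt <- unique(round(diff(bg$time_min), 9))
  if (length(dt) != 1L)
    stopf("simulate_cgm requires a uniform BG grid")
  step <- cgm_period / dt
  if (abs(step - round(step)) > 1e-9)
    stopf("cgm_period must be a multiple of the BG grid step")
  ig <- bg_to_ig(bg, params$kinetics)
  igs <- apply_calibration(ig, params$cal)
  keep <- seq(1L, nrow(igs), by = round(step))
  times <- igs$time_min[keep]
  clean <- igs$glucose_mg_dl[keep]
  v <- if (params$noise$sigma > 0) {
    simulate_ar_noise(params$noise, length(keep), seed = seed)
  } else rep.int(0, length(keep))
  raw <- clean + v
  clipped <- pmin(pmax(raw, 40), 400)
  out <- glucose_trace(times, clipped, rep.int(1L, length(times)),
                       period = cgm_period)
  attr(out, "saturated") <- raw <= 40 | raw >= 400
  out
}

## ---- parameter JSON I/O -----------------------------------------------------

#' Read / write sensor-error parameters as JSON
#'
#' Schema: an object with keys `tau_min`, `cal_spec` (`a_family`,
#' `b_family`), `a_coeffs`, `b_coeffs`, `ar_coeffs`, `sigma_mg_dl`,
#' `period_min`.
#'
#' @param path File path.
#' @return `read_params_json` returns a [sensor_error_params()].
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- cal_spec(x$cal_spec$a_family, x$cal_spec$b_family)
  sensor_error_params(
    kinetics = kinetics_params(x$tau_min),
    cal = cal_params(spec, x$a_coeffs, x$b_coeffs),
    noise = ar_noise_params(x$ar_coeffs, x$sigma_mg_dl,
                            period = if (is.null(x$period_min)) 5 else x$period_min))
}

#' @rdname read_params_json
#' @param params A [sensor_error_params()].
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(list(
    tau_min = params$kinetics$tau,
    cal_spec = list(a_family = params$cal$spec$a_family,
                    b_family = params$cal$spec$b_family),
    a_coeffs = params$cal$a_coeffs,
    b_coeffs = params$cal$b_coeffs,
    ar_coeffs = params$noise$alpha,
    sigma_mg_dl = params$noise$sigma,
    period_min = params$noise$period
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
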