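## Estimation of the full sensor-error parameter set from matched
## (reference BG, CGM) pairs: two-step (kinetics+calibration by nonlinear
## least squares, then AR noise on the residuals) and single-step (all
## parameters jointly, under the AR stationarity constraint).

## ---- theta packing ---------------------------------------------------------

family_coef_names <- function(family, prefix) {
  if (family == "exp") paste0(prefix, c("_init", "_final", "_tc"))
  else paste0(prefix, seq_len(family_n_params(family)) - 1L)
}

theta_names <- function(spec) {
  c("tau", family_coef_names(spec$a_family, "a"),
    family_coef_names(spec$b_family, "b"))
}

theta_default <- function(spec) {
  # tau = 7 min, a(t) = 1, b(t) = 0
  a <- switch(spec$a_family,
              exp = c(1, 1, 2),
              c(1, rep.int(0, family_n_params(spec$a_family) - 1L)))
  b <- switch(spec$b_family,
              exp = c(0, 0, 2),
              rep.int(0, family_n_params(spec$b_family)))
  stats::setNames(c(7, a, b), theta_names(spec))
}

theta_bounds <- function(spec, tau_bounds = c(0, 60)) {
  fam_lower <- function(family) {
    if (family == "exp") c(-Inf, -Inf, 0.05) else
      rep.int(-Inf, family_n_params(family))
  }
  fam_upper <- function(family) {
    if (family == "exp") c(Inf, Inf, 50) else
      rep.int(Inf, family_n_params(family))
  }
  list(lower = c(tau_bounds[1L], fam_lower(spec$a_family), fam_lower(spec$b_family)),
       upper = c(tau_bounds[2L], fam_upper(spec$a_family), fam_upper(spec$b_family)))
}

theta_scale <- function(spec) {
  fam_scale <- function(family, gain) {
    if (family == "exp") {
      if (gain) c(1, 1, 1) else c(10, 10, 1)
    } else {
      base <- if (gain) c(1, 0.05, 0.01, 0.005) else c(10, 1, 0.2, 0.1)
      base[seq_len(family_n_params(family))]
    }
  }
  c(10, fam_scale(spec$a_family, TRUE), fam_scale(spec$b_family, FALSE))
}

unpack_theta <- function(theta, spec) {
  na <- family_n_params(spec$a_family)
  nb <- family_n_params(spec$b_family)
  list(tau = theta[1L],
       a_coeffs = theta[1L + seq_len(na)],
       b_coeffs = theta[1L + na + seq_len(nb)])
}

## ---- model prediction -------------------------------------------------------

#' Predict the noiseless sensor signal at CGM times
#'
#' Convolves each segment's 1-min reference BG series with the first-order
#' kinetic impulse response, applies the calibration gain/offset, and reads
#' the result at the CGM sampling times.
#'
#' @param tau Kinetic time constant (minutes).
#' @param cal A [cal_params()].
#' @param pairs A [match_cgm()] result (carries per-segment 1-min reference
#'   series).
#' @return Numeric prediction at each matched CGM time, in pair order.
#' @export
predict_igs <- function(tau, cal, pairs) {
  out <- numeric(length(pairs$times))
  seg_levels <- sort(unique(pairs$segment_ids))
  for (s in seq_along(seg_levels)) {
    ii <- which(pairs$segment_ids == seg_levels[s])
    ref <- pairs$ref_segments[[s]]
    rt <- ref$times
    ig <- if (tau > 0 && length(rt) > 1L) {
      dt <- rt[2L] - rt[1L]
      phi <- exp(-dt / tau)
      as.numeric(stats::filter((1 - phi) * ref$values, phi,
                               method = "recursive", init = ref$values[1L]))
    } else ref$values
    idx <- round((pairs$times[ii] - rt[1L]) / (if (length(rt) > 1L) rt[2L] - rt[1L] else 1)) + 1L
    if (any(idx < 1L | idx > length(rt)))
      stopf("CGM time outside the reference coverage of its segment")
    ab <- eval_calibration(cal, pairs$times[ii])
    out[ii] <- ab$a * ig[idx] + ab$b
  }
  out
}

residuals_by_segment <- function(r, segment_ids) {
  # numeric-ordered levels: plain split() would sort "10" before "2"
  split(r, factor(segment_ids, levels = sort(unique(segment_ids))))
}

## ---- step 1: nonlinear least squares ---------------------------------------

#' First identification step: kinetics and calibration by nonlinear LS
#'
#' Minimises the raw residual sum of squares `sum_j (ys_j - y_j(theta))^2`
#' over theta = (tau, calibration coefficients) with the Levenberg-Marquardt
#' algorithm, tau box-bounded in `tau_bounds`. Default initial values:
#' tau = 7 min, a(t) = 1, b(t) = 0.
#'
#' @param pairs A [match_cgm()] result.
#' @param spec A [cal_spec()].
#' @param init Optional named initial theta vector (same layout as the
#'   returned `theta`).
#' @param tau_bounds Bounds on tau in minutes (default `c(0, 60)`).
#' @return List with `theta` (named estimate), `tau`, `cal`, `residuals`
#'   (per-segment raw residuals), `rss`, `converged`, `n_used`.
#' @export
fit_step1 <- function(pairs, spec, init = NULL, tau_bounds = c(0, 60)) {
  n <- length(pairs$times)
  np <- n_cal_params(spec)
  if (n < np + 2L)
    stopf("need at least %d matched pairs to fit %d calibration parameters + tau",
          np + 2L, np)
  theta0 <- if (is.null(init)) theta_default(spec) else init
  bounds <- theta_bounds(spec, tau_bounds)
  resid_fun <- function(theta) {
    u <- unpack_theta(theta, spec)
    cal <- cal_params(spec, u$a_coeffs, u$b_coeffs)
    pairs$cgm - predict_igs(u$tau, cal, pairs)
  }
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fun,
                            lower = bounds$lower, upper = bounds$upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-10))
  theta <- stats::setNames(as.numeric(fit$par), theta_names(spec))
  r <- resid_fun(theta)
  converged <- fit$info %in% 1:4
  if (!converged)
    warnf("step-1 fit did not converge (nls.lm info %d); best iterate returned",
          fit$info)
  u <- unpack_theta(theta, spec)
  list(theta = theta, tau = u$tau,
       cal = cal_params(spec, u$a_coeffs, u$b_coeffs),
       residuals = residuals_by_segment(r, pairs$segment_ids),
       rss = sum(r^2), converged = converged, n_used = n)
}

## ---- AR fitting -------------------------------------------------------------

# Levinson step-up: reflection coefficients -> AR prediction coefficients.
reflection_to_ar <- function(k) {
  a <- numeric()
  for (m in seq_along(k)) {
    a <- if (m == 1L) k[1L] else c(a - k[m] * rev(a), k[m])
  }
  a
}

# Levinson step-down: AR coefficients -> reflection coefficients.
ar_to_reflection <- function(alpha) {
  q <- length(alpha)
  k <- numeric(q)
  a <- alpha
  for (m in rev(seq_len(q))) {
    k[m] <- a[m]
    if (m > 1L) {
      denom <- 1 - k[m]^2
      a <- (a[seq_len(m - 1L)] + k[m] * rev(a[seq_len(m - 1L)])) / denom
    }
  }
  k
}

# Project AR coefficients into the stationarity region with the given margin
# by clipping their reflection coefficients.
stabilize_ar <- function(alpha, margin = 1e-3) {
  if (ar_is_stationary(alpha, margin)) return(alpha)
  k <- suppressWarnings(ar_to_reflection(alpha))
  if (anyNA(k) || any(!is.finite(k))) k <- rep.int(0, length(alpha))
  k <- pmin(pmax(k, -1 + margin), 1 - margin)
  reflection_to_ar(k)
}

#' Fit an AR(q) model to per-segment residuals by forward-backward LS
#'
#' Modified-covariance (forward-backward) least squares: the AR coefficients
#' minimise the summed squared forward and backward one-step prediction
#' errors. Segments are treated independently; no lag products cross a
#' segment boundary. `sigma` is the sample SD of the forward one-step
#' prediction errors.
#'
#' @param residuals List of numeric per-segment residual series (a single
#'   vector is treated as one segment).
#' @param q AR order.
#' @param period Sampling period (minutes) recorded in the returned object.
#' @return An [ar_noise_params()]; attribute `rss` holds the forward
#'   prediction-error sum of squares and `n_eff` the number of forward
#'   prediction errors.
#' @export
fit_ar <- function(residuals, q, period = 5) {
  if (!is.list(residuals)) residuals <- list(residuals)
  usable <- residuals[lengths(residuals) >= q + 1L]
  pooled <- sum(lengths(usable))
  if (pooled < 10L * q)
    stopf("AR(%d) fit needs a pooled residual length of at least %d", q, 10L * q)
  rows_f <- list(); rows_b <- list(); y_f <- list(); y_b <- list()
  for (x in usable) {
    n <- length(x)
    idx <- (q + 1L):n
    Xf <- sapply(seq_len(q), function(j) x[idx - j])
    rows_f[[length(rows_f) + 1L]] <- matrix(Xf, ncol = q)
    y_f[[length(y_f) + 1L]] <- x[idx]
    idx_b <- 1L:(n - q)
    Xb <- sapply(seq_len(q), function(j) x[idx_b + j])
    rows_b[[length(rows_b) + 1L]] <- matrix(Xb, ncol = q)
    y_b[[length(y_b) + 1L]] <- x[idx_b]
  }
  X <- rbind(do.call(rbind, rows_f), do.call(rbind, rows_b))
  y <- c(unlist(y_f), unlist(y_b))
  qr_fit <- qr(X)
  if (qr_fit$rank < q) stopf("rank-deficient AR design (order %d)", q)
  alpha <- as.numeric(qr.coef(qr_fit, y))
  # forward one-step prediction errors
  ef <- unlist(mapply(function(Xs, ys) ys - as.numeric(Xs %*% alpha),
                      rows_f, y_f, SIMPLIFY = FALSE))
  out <- ar_noise_params(stabilize_ar(alpha), stats::sd(ef), period = period)
  attr(out, "rss") <- sum(ef^2)
  attr(out, "n_eff") <- length(ef)
  attr(out, "se") <- tryCatch({
    s2 <- sum(ef^2) / max(length(ef) - q, 1L)
    sqrt(diag(s2 * chol2inv(qr.R(qr_fit))))
  }, error = function(e) rep.int(NA_real_, q))
  out
}

#' Whiten residuals with an AR(2) inverse filter
#'
#' Fits a single AR(2) model to the pooled per-segment residuals (forward-
#' backward least squares, no cross-segment lags) and outputs
#' `wr_j = r_j - a1 r_{j-1} - a2 r_{j-2}` for `j >= 3` within each segment;
#' the first two residuals of every segment are dropped. An unstable fitted
#' AR(2) is projected just inside the stationarity region (margin 1e-3).
#'
#' @param residuals List of per-segment residual series.
#' @return List with `whitened` (per-segment series), `alpha` (whitening
#'   coefficients), `rss` (whitened residual sum of squares) and `n`
#'   (whitened-residual count).
#' @export
whiten_residuals <- function(residuals) {
  if (!is.list(residuals)) residuals <- list(residuals)
  short <- lengths(residuals) < 3L
  if (any(short))
    warnf("%d segment(s) shorter than 3 residuals contribute nothing to whitening",
          sum(short))
  ar2 <- fit_ar(residuals[!short], 2L)
  alpha <- ar2$alpha
  whitened <- lapply(residuals[!short], function(x) {
    j <- 3L:length(x)
    x[j] - alpha[1L] * x[j - 1L] - alpha[2L] * x[j - 2L]
  })
  list(whitened = whitened, alpha = alpha,
       rss = sum(unlist(whitened)^2), n = length(unlist(whitened)))
}

#' Bayesian Information Criterion for a residual sum of squares
#'
#' `BIC = n log(rss / n) + (n_params + 1) log(n)`. For calibration-model
#' selection `n_params` is the calibration-coefficient count N_p and the
#' `+1` accounts for tau; for AR-order selection pass `n_params = q` and the
#' `+1` accounts for sigma. `rss` must be the whitened residual sum of
#' squares and `n` the number of residuals entering it.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of residuals (> n_params).
#' @param n_params Count of model parameters (excluding the one the +1
#'   covers).
#' @return The BIC value; `-Inf` with attribute `degenerate = TRUE` when
#'   `rss` is exactly 0.
#' @export
compute_bic <- function(rss, n, n_params) {
  if (n <= n_params) stopf("BIC needs n > n_params")
  if (rss < 0) stopf("rss must be >= 0")
  if (rss == 0) return(structure(-Inf, degenerate = TRUE))
  n * log(rss / n) + (n_params + 1) * log(n)
}

#' Select the AR order of the residual noise by BIC
#'
#' Fits AR(q) for q = 1..`q_max` by forward-backward least squares and
#' computes `BIC = n log(rss/n) + (q + 1) log(n)` from the forward one-step
#' prediction errors; orders whose pooled sample requirement (10 q) exceeds
#' the data are skipped.
#'
#' @param residuals List of per-segment residual series.
#' @param q_max Largest candidate order (default 10).
#' @return List with `order` (the argmin), `bic` (named per-order values)
#'   and `fits` (the per-order [fit_ar()] results).
#' @export
select_ar_order <- function(residuals, q_max = 10L) {
  if (!is.list(residuals)) residuals <- list(residuals)
  pooled <- sum(lengths(residuals))
  orders <- seq_len(q_max)
  orders <- orders[10L * orders <= pooled]
  if (length(orders) == 0L) stopf("not enough residuals for any AR order")
  fits <- lapply(orders, function(q) fit_ar(residuals, q))
  bic <- vapply(seq_along(orders), function(i) {
    compute_bic(attr(fits[[i]], "rss"), attr(fits[[i]], "n_eff"), orders[i])
  }, numeric(1L))
  names(bic) <- orders
  list(order = orders[which.min(bic)], bic = bic,
       fits = stats::setNames(fits, orders))
}

## ---- full procedures --------------------------------------------------------

whiten_with <- function(residuals, alpha) {
  q <- length(alpha)
  keep <- lengths(residuals) > q
  lapply(residuals[keep], function(x) {
    j <- (q + 1L):length(x)
    w <- x[j]
    for (k in seq_len(q)) w <- w - alpha[k] * x[j - k]
    w
  })
}

# Gauss-Markov standard errors of theta from the numeric Jacobian of the
# whitened residual vector at the optimum.
theta_se <- function(theta, spec, pairs, alpha, sigma2) {
  base_wr <- function(th) {
    u <- unpack_theta(th, spec)
    r <- pairs$cgm - predict_igs(u$tau, cal_params(spec, u$a_coeffs, u$b_coeffs), pairs)
    unlist(whiten_with(residuals_by_segment(r, pairs$segment_ids), alpha))
  }
  f0 <- base_wr(theta)
  J <- matrix(0, length(f0), length(theta))
  h <- pmax(abs(theta) * 1e-5, 1e-7)
  for (j in seq_along(theta)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    J[, j] <- (base_wr(tp) - base_wr(tm)) / (2 * h[j])
  }
  se <- tryCatch(sqrt(diag(sigma2 * chol2inv(chol(crossprod(J))))),
                 error = function(e) rep.int(NA_real_, length(theta)))
  stats::setNames(se, names(theta))
}

make_fit_result <- function(method, spec, theta, alpha, sigma, pairs,
                            residuals, whitened, rss_whitened, n_used,
                            converged, se, period = 5) {
  u <- unpack_theta(theta, spec)
  params <- sensor_error_params(
    kinetics = kinetics_params(u$tau),
    cal = cal_params(spec, u$a_coeffs, u$b_coeffs),
    noise = ar_noise_params(alpha, sigma, period = period))
  est <- c(theta, stats::setNames(alpha, paste0("alpha", seq_along(alpha))),
           sigma = sigma)
  cv <- se / abs(est[names(se)])
  structure(list(method = method, params = params, theta = theta,
                 estimates = est, pair_times = pairs$times,
                 pair_cgm = pairs$cgm,
                 residuals = residuals, whitened = whitened,
                 rss_whitened = rss_whitened,
                 bic = compute_bic(rss_whitened, n_used, n_cal_params(spec)),
                 n_used = n_used, converged = converged,
                 se = se, cv_of_estimates = cv),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s, whitened RSS %.2f on %d residuals, BIC %.1f%s\n",
              x$method, x$rss_whitened, x$n_used, x$bic,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$estimates, 4))
  invisible(x)
}

#' @export
coef.fit_result <- function(object, ...) object$estimates

#' Two-step identification of the full sensor-error model
#'
#' Step one estimates the kinetic time constant and calibration coefficients
#' by nonlinear least squares ([fit_step1()]); its residuals are whitened
#' with an AR(2) inverse filter to produce the whitened RSS and BIC used in
#' model selection; the noise model itself is an AR(`q`) fitted to the raw
#' step-one residuals by forward-backward least squares.
#'
#' @param pairs A [match_cgm()] result.
#' @param spec A [cal_spec()].
#' @param q AR noise order (default 2).
#' @param init Optional initial theta for step one.
#' @return A `fit_result` with the assembled [sensor_error_params()], raw
#'   and whitened residuals, whitened RSS, BIC, approximate standard errors
#'   and per-parameter CV of the estimation error.
#' @export
two_step_identify <- function(pairs, spec, q = 2L, init = NULL) {
  s1 <- fit_step1(pairs, spec, init = init)
  wh <- whiten_residuals(s1$residuals)
  ar <- fit_ar(s1$residuals, q)
  sigma2 <- wh$rss / max(wh$n - length(s1$theta), 1L)
  se_theta <- theta_se(s1$theta, spec, pairs, wh$alpha, sigma2)
  se <- c(se_theta,
          stats::setNames(attr(ar, "se"), paste0("alpha", seq_len(q))),
          sigma = ar$sigma / sqrt(2 * max(attr(ar, "n_eff") - 1L, 1L)))
  make_fit_result("two-step", spec, s1$theta, ar$alpha, ar$sigma, pairs,
                  residuals = s1$residuals, whitened = wh$whitened,
                  rss_whitened = wh$rss, n_used = wh$n,
                  converged = s1$converged, se = se,
                  period = ar$period)
}

#' Single-step identification of the full sensor-error model
#'
#' Jointly minimises the whitened residual sum of squares
#' `sum_j [ r_j(theta) - sum_k alpha_k r_{j-k}(theta) ]^2` over the kinetic,
#' calibration and AR parameters, with lag terms confined within segments
#' (the first `q` pairs of each segment are excluded from the sum) and the
#' AR coefficients constrained to the stationarity region: internally they
#' are represented by reflection (partial autocorrelation) coefficients
#' box-bounded in `[-1 + 1e-3, 1 - 1e-3]`, which maps exactly onto the
#' stationarity region with a 1e-3 margin (for q = 2, the open triangle
#' `alpha1 + alpha2 < 1`, `alpha2 - alpha1 < 1`, `|alpha2| < 1`). The
#' optimizer is gradient-based bound-constrained quasi-Newton (L-BFGS-B).
#' `sigma` is the sample SD of the whitened residuals at the optimum.
#'
#' By default theta starts at the two-step solution and alpha at the
#' two-step AR fit (falling back to (1.30, -0.42) for q = 2 if that fit is
#' unusable), so the optimised objective can never exceed the two-step
#' whitened RSS. `init_theta = "defaults"` restores the tau = 7 min,
#' a(t) = 1, b(t) = 0 start instead.
#'
#' @param pairs A [match_cgm()] result.
#' @param spec A [cal_spec()].
#' @param q AR order (default 2).
#' @param two_step Optional precomputed [two_step_identify()] result on the
#'   same pairs (avoids refitting).
#' @param init_theta `"two-step"` (default) or `"defaults"`.
#' @param tau_bounds Bounds on tau in minutes.
#' @return A `fit_result` (see [two_step_identify()]); element `objective`
#'   holds the optimised whitened RSS.
#' @export
single_step_identify <- function(pairs, spec, q = 2L, two_step = NULL,
                                 init_theta = c("two-step", "defaults"),
                                 tau_bounds = c(0, 60)) {
  init_theta <- match.arg(init_theta)
  margin <- 1e-3
  if (is.null(two_step) && (init_theta == "two-step"))
    two_step <- two_step_identify(pairs, spec, q = q)
  theta0 <- if (init_theta == "two-step") two_step$theta else theta_default(spec)
  alpha0 <- if (!is.null(two_step) && length(two_step$params$noise$alpha) == q &&
                ar_is_stationary(two_step$params$noise$alpha, margin)) {
    two_step$params$noise$alpha
  } else if (q == 2L) c(1.30, -0.42) else rep.int(0, q)
  k0 <- pmin(pmax(ar_to_reflection(alpha0), -1 + margin), 1 - margin)
  nt <- length(theta0)
  bounds <- theta_bounds(spec, tau_bounds)
  lower <- c(bounds$lower, rep.int(-1 + margin, q))
  upper <- c(bounds$upper, rep.int(1 - margin, q))
  objective <- function(par) {
    u <- unpack_theta(par[seq_len(nt)], spec)
    alpha <- reflection_to_ar(par[nt + seq_len(q)])
    r <- pairs$cgm - predict_igs(u$tau, cal_params(spec, u$a_coeffs, u$b_coeffs), pairs)
    sum(unlist(whiten_with(residuals_by_segment(r, pairs$segment_ids), alpha))^2)
  }
  par0 <- c(theta0, k0)
  opt <- stats::optim(par0, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 400,
                                     parscale = c(theta_scale(spec),
                                                  rep.int(0.2, q)),
                                     factr = 1e5))
  converged <- opt$convergence == 0L
  if (!converged)
    warnf("single-step optimisation did not fully converge (optim code %d)",
          opt$convergence)
  theta <- stats::setNames(opt$par[seq_len(nt)], theta_names(spec))
  alpha <- reflection_to_ar(opt$par[nt + seq_len(q)])
  u <- unpack_theta(theta, spec)
  r <- pairs$cgm - predict_igs(u$tau, cal_params(spec, u$a_coeffs, u$b_coeffs), pairs)
  res_seg <- residuals_by_segment(r, pairs$segment_ids)
  wr_seg <- whiten_with(res_seg, alpha)
  wr <- unlist(wr_seg)
  sigma <- stats::sd(wr)
  sigma2 <- sum(wr^2) / max(length(wr) - nt - q, 1L)
  se_theta <- theta_se(theta, spec, pairs, alpha, sigma2)
  # alpha SEs from a local AR regression of the raw residuals at the optimum
  se_alpha <- tryCatch({
    ar_loc <- fit_ar(res_seg, q)
    stats::setNames(attr(ar_loc, "se"), paste0("alpha", seq_len(q)))
  }, error = function(e) stats::setNames(rep.int(NA_real_, q),
                                         paste0("alpha", seq_len(q))))
  se <- c(se_theta, se_alpha,
          sigma = sigma / sqrt(2 * max(length(wr) - 1L, 1L)))
  out <- make_fit_result("single-step", spec, theta, alpha, sigma, pairs,
                         residuals = res_seg, whitened = wr_seg,
                         rss_whitened = sum(wr^2), n_used = length(wr),
                         converged = converged, se = se)
  out$objective <- opt$value
  out
}

## ---- comparisons ------------------------------------------------------------

#' Compare two fits of the same sensor
#'
#' @param a,b `fit_result` objects fitted on the same matched pairs
#'   (conventionally `a` = two-step, `b` = single-step).
#' @return List with each fit's RMSE of raw residuals, the whitened-RSS
#'   difference `b - a` (negative = `b` fits better) and the estimate
#'   vectors.
#' @export
compare_fits <- function(a, b) {
  if (!isTRUE(all.equal(a$pair_times, b$pair_times)) ||
      !isTRUE(all.equal(a$pair_cgm, b$pair_cgm)))
    stopf("fits were not computed on the same pairs")
  list(rmse_a = sqrt(mean(unlist(a$residuals)^2)),
       rmse_b = sqrt(mean(unlist(b$residuals)^2)),
       rss_diff = b$rss_whitened - a$rss_whitened,
       estimates_a = a$estimates, estimates_b = b$estimates)
}

#' Compare two identification procedures across a sensor cohort
#'
#' Computes per-sensor whitened-RSS differences (`b - a`), an exact binomial
#' sign test on their signs, and the per-parameter Pearson correlation
#' between the two procedures' estimates.
#'
#' @param fits_a,fits_b Lists of `fit_result` objects, one pair per sensor.
#' @return List with `rss_diff`, `sign_test` (an `htest`), `frac_improved`
#'   (share of sensors with `rss_diff <= 0`) and `correlations`.
#' @export
compare_cohort <- function(fits_a, fits_b) {
  if (length(fits_a) != length(fits_b)) stopf("cohorts differ in size")
  cmp <- Map(compare_fits, fits_a, fits_b)
  d <- vapply(cmp, `[[`, numeric(1L), "rss_diff")
  nz <- d[d != 0]
  st <- if (length(nz) > 0L) stats::binom.test(sum(nz < 0), length(nz)) else
    structure(list(p.value = 1, statistic = c("number of successes" = 0),
                   method = "Exact binomial test (no nonzero differences)"),
              class = "htest")
  pars <- Reduce(intersect, lapply(c(fits_a, fits_b),
                                   function(f) names(f$estimates)))
  A <- sapply(pars, function(p) vapply(fits_a, function(f) f$estimates[[p]],
                                       numeric(1L)))
  B <- sapply(pars, function(p) vapply(fits_b, function(f) f$estimates[[p]],
                                       numeric(1L)))
  rho <- vapply(pars, function(p) {
    if (stats::sd(A[, p]) == 0 || stats::sd(B[, p]) == 0) NA_real_
    else stats::cor(A[, p], B[, p])
  }, numeric(1L))
  list(rss_diff = d, sign_test = st, frac_improved = mean(d <= 0),
       correlations = rho)
}
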