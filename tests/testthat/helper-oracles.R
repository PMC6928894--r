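# Independent closed-form oracles used across the tests.

# Exact first-order step response under zero-order-hold semantics: the input
# is held at its new level from the sample *after* the change onward, so the
# effective step time is one grid step before the first changed sample.
oracle_step_response <- function(times, t_change, dt, from, to, tau) {
  ifelse(times < t_change, from,
         to - (to - from) * exp(-(times - (t_change - dt)) / tau))
}

# Yule-Walker closed forms for a stationary AR(2) process.
oracle_ar2_variance <- function(alpha, sigma) {
  a1 <- alpha[1L]; a2 <- alpha[2L]
  sigma^2 * (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
}
oracle_ar2_rho <- function(alpha, lag) {
  a1 <- alpha[1L]; a2 <- alpha[2L]
  rho <- c(1, a1 / (1 - a2))
  if (lag > 1L)
    for (k in seq(3L, lag + 1L))
      rho[k] <- a1 * rho[k - 1L] + a2 * rho[k - 2L]
  rho[lag + 1L]
}

# Continuous-convolution quadrature oracle for IG = h (*) BG: trapezoidal
# quadrature of BG(s) * exp(-(t-s)/tau)/tau on a fine grid, with the
# steady-state initial condition IG(t0) = BG(t0) carried explicitly.
oracle_ig_quadrature <- function(bg_fun, t0, t, tau, dt = 0.01) {
  vapply(t, function(tt) {
    if (tt == t0) return(bg_fun(t0))
    s <- seq(t0, tt, by = dt)
    f <- bg_fun(s) * exp(-(tt - s) / tau) / tau
    bg_fun(t0) * exp(-(tt - t0) / tau) +
      sum((f[-1L] + f[-length(f)]) / 2 * diff(s))
  }, numeric(1L))
}

# Small synthetic sensor for identification tests, parameters at the
# published single-step cohort medians unless overridden. Returns matched
# pairs built on the true BG plus the truth. With `session_locked = TRUE`
# each clinical session is simulated independently with the same
# steady-state initial condition the estimator assumes, so the matched
# pairs are generated by exactly the model being fitted (used by the
# zero-noise recovery oracles); otherwise the CGM trace is simulated
# continuously over the whole wear.
tiny_sensor <- function(seed = 1L, sigma = 3.19, tau = 3.78,
                        a_coeffs = c(0.95, 0.004, 0), b_coeffs = 6.35,
                        alpha = c(1.30, -0.42),
                        spec = cal_spec("poly2", "poly0"),
                        design = study_design(), session_locked = FALSE) {
  truth <- sensor_error_params(
    kinetics_params(tau),
    cal_params(spec, a_coeffs, b_coeffs),
    ar_noise_params(alpha, sigma, period = design$cgm_period_min))
  bg <- generate_bg(design$wear_days, seed = seed)
  if (!session_locked) {
    cgm <- simulate_cgm(bg, truth, cgm_period = design$cgm_period_min,
                        seed = seed + 1L)
    return(list(pairs = true_bg_pairs(bg, cgm, design), truth = truth,
                bg = bg, cgm = cgm))
  }
  sel <- lapply(seq_len(nrow(design$session_bounds)), function(s)
    which(bg$time_min >= design$session_bounds[s, 1L] &
            bg$time_min <= design$session_bounds[s, 2L]))
  bg_sess <- glucose_trace(bg$time_min[unlist(sel)],
                           bg$glucose_mg_dl[unlist(sel)],
                           rep(seq_along(sel), lengths(sel)), period = 1)
  igs <- apply_calibration(bg_to_ig(bg_sess, truth$kinetics), truth$cal)
  cgm_keep <- which(igs$time_min %% design$cgm_period_min == 0)
  v <- if (sigma > 0) simulate_ar_noise(truth$noise, length(cgm_keep),
                                        seed = seed + 1L) else 0
  pairs <- structure(list(
    times = igs$time_min[cgm_keep],
    reference = bg_sess$glucose_mg_dl[cgm_keep],
    cgm = igs$glucose_mg_dl[cgm_keep] + v,
    segment_ids = igs$segment_id[cgm_keep],
    ref_segments = lapply(sel, function(ii)
      list(times = bg$time_min[ii], values = bg$glucose_mg_dl[ii]))),
    class = "matched_pairs")
  list(pairs = pairs, truth = truth, bg = bg, cgm = NULL)
}
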