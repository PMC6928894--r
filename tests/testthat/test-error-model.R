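test_that("kinetic convolution preserves constants and reduces to identity", {
  t <- 0:600
  const <- glucose_trace(t, rep(120, length(t)), period = 1)
  for (tau in c(0, 3.78, 10, 45)) {
    expect_equal(bg_to_ig(const, tau)$glucose_mg_dl, rep(120, length(t)))
  }
  set.seed(11)
  wiggly <- glucose_trace(t, 150 + 40 * sin(t / 90) + rnorm(length(t)),
                          period = 1)
  expect_identical(bg_to_ig(wiggly, 0)$glucose_mg_dl, wiggly$glucose_mg_dl)
})

test_that("kinetic step response matches the closed form", {
  t <- 0:120
  bg <- ifelse(t < 60, 100, 180)
  ig <- bg_to_ig(glucose_trace(t, bg, period = 1), 10)
  expect_lt(max(abs(ig$glucose_mg_dl -
                      oracle_step_response(t, 60, 1, 100, 180, 10))), 0.5)
})

test_that("kinetic convolution rejects bad grids and negative tau", {
  bad <- glucose_trace(c(0, 1, 3, 4), c(100, 100, 100, 100))
  expect_error(bg_to_ig(bad, 5), "uniform")
  ok <- glucose_trace(0:3, rep(100, 4), period = 1)
  expect_error(bg_to_ig(ok, -1), "tau")
})

test_that("interstitial glucose lags a rising ramp and refines consistently", {
  t <- 0:720
  ramp <- glucose_trace(t, 100 + 0.15 * t, period = 1)
  ig <- bg_to_ig(ramp, 8)
  interior <- 2:length(t)
  expect_true(all(ig$glucose_mg_dl[interior] <
                    ramp$glucose_mg_dl[interior]))
  # discretization consistency: 1-min vs 0.1-min grid on a smooth profile
  tf <- seq(0, 720, by = 0.1)
  smooth_fun <- function(x) 140 + 20 * sin(2 * pi * x / 720)
  coarse <- bg_to_ig(glucose_trace(t, smooth_fun(t), period = 1), 10)
  fine <- bg_to_ig(glucose_trace(tf, smooth_fun(tf), period = 0.1), 10)
  expect_lt(max(abs(coarse$glucose_mg_dl -
                      fine$glucose_mg_dl[match(t, round(tf, 6))])), 0.1)
})

test_that("calibration families evaluate to their stated forms", {
  s_pp <- cal_spec("poly0", "poly0")
  ab <- eval_calibration(cal_params(s_pp, 0.95, 7.30), c(0, 1440, 7200))
  expect_equal(ab$a, rep(0.95, 3))
  expect_equal(ab$b, rep(7.30, 3))
  s2 <- cal_spec("poly2", "poly0")
  ab2 <- eval_calibration(cal_params(s2, c(1, 0, 0), 0), seq(0, 14400, 720))
  expect_equal(ab2$a, rep(1, 21))
  # quadratic in days: a(5 days) = a0 + 5 a1 + 25 a2
  ab3 <- eval_calibration(cal_params(s2, c(0.9, 0.02, 0.001), 0), 5 * 1440)
  expect_equal(ab3$a, 0.9 + 0.02 * 5 + 0.001 * 25)
  se <- cal_spec("exp", "poly0")
  abe <- eval_calibration(cal_params(se, c(1.2, 0.8, 2), 0), 2 * 1440)
  expect_equal(abe$a, 0.8 + 0.4 * exp(-1))
  expect_error(cal_params(s2, c(1, 0), 0), "coefficients")
  expect_error(cal_params(se, c(1, 1, -1), 0), "time constant")
})

test_that("calibration distorts the signal as a(t) * IG + b(t)", {
  t <- seq(0, 14400, by = 5)
  ig <- glucose_trace(t, rep(100, length(t)), period = 5)
  s <- cal_spec("poly0", "poly0")
  out <- apply_calibration(ig, cal_params(s, 0.95, 7.30))
  expect_equal(out$glucose_mg_dl, rep(102.3, length(t)))
  ident <- apply_calibration(ig, cal_params(s, 1, 0))
  expect_equal(ident$glucose_mg_dl, ig$glucose_mg_dl)
  s1 <- cal_spec("poly1", "poly0")
  drift <- apply_calibration(ig, cal_params(s1, c(1, 0.01), 2))
  at5d <- which(t == 5 * 1440)
  expect_equal(drift$glucose_mg_dl[at5d], 100 * 1.05 + 2)
})

test_that("AR noise simulation matches Yule-Walker closed forms", {
  # white noise limit
  w <- simulate_ar_noise(ar_noise_params(numeric(), 1), 5e4, seed = 1)
  expect_lt(abs(sd(w) - 1), 0.02)
  # AR(1) stationary variance sigma^2 / (1 - a1^2)
  v1 <- simulate_ar_noise(ar_noise_params(0.5, 1), 2e5, seed = 2)
  expect_lt(abs(var(v1) - 1 / 0.75) / (1 / 0.75), 0.02)
  # AR(2) at the published noise medians: variance and lag-1 correlation
  al <- c(1.30, -0.42)
  v2 <- simulate_ar_noise(ar_noise_params(al, 3.19), 2e5, seed = 3)
  expect_lt(abs(var(v2) - oracle_ar2_variance(al, 3.19)) /
              oracle_ar2_variance(al, 3.19), 0.02)
  r1 <- cor(v2[-1], v2[-length(v2)])
  expect_lt(abs(r1 - oracle_ar2_rho(al, 1)), 0.02)
  # determinism
  expect_identical(v1, simulate_ar_noise(ar_noise_params(0.5, 1), 2e5, seed = 2))
})

test_that("non-stationary AR coefficients are rejected", {
  expect_error(ar_noise_params(c(1.2, -0.2), 1), "unit circle")
  expect_error(ar_noise_params(1.0, 1), "unit circle")
  expect_true(ar_is_stationary(c(1.30, -0.42)))
  expect_false(ar_is_stationary(c(0.6, 0.5)))
})

test_that("the forward simulator composes the three error blocks", {
  t <- 0:(2 * 1440)
  bg <- glucose_trace(t, 120 + 30 * sin(2 * pi * t / 480), period = 1)
  spec <- cal_spec("poly0", "poly0")
  off <- sensor_error_params(kinetics_params(0),
                             cal_params(spec, 1, 0),
                             ar_noise_params(numeric(), 0))
  cgm <- simulate_cgm(bg, off, cgm_period = 5)
  expect_equal(cgm$glucose_mg_dl, bg$glucose_mg_dl[seq(1, nrow(bg), 5)])
  expect_equal(attr(cgm, "period"), 5)
  # steady state with gain 0.9, offset 10, tau 10 on constant BG 200
  bgc <- glucose_trace(t, rep(200, length(t)), period = 1)
  par2 <- sensor_error_params(kinetics_params(10),
                              cal_params(spec, 0.9, 10),
                              ar_noise_params(numeric(), 0))
  cgm2 <- simulate_cgm(bgc, par2, cgm_period = 5)
  late <- cgm2$time_min > 60
  expect_equal(cgm2$glucose_mg_dl[late], rep(190, sum(late)))
  # within-trace noise SD matches the AR(2) stationary SD
  parn <- sensor_error_params(kinetics_params(0), cal_params(spec, 1, 0),
                              ar_noise_params(c(1.30, -0.42), 3.19))
  bg10 <- glucose_trace(0:14400, rep(150, 14401), period = 1)
  cgmn <- simulate_cgm(bg10, parn, cgm_period = 5, seed = 9)
  noise <- cgmn$glucose_mg_dl - 150
  expect_lt(abs(sd(noise) - sqrt(oracle_ar2_variance(c(1.30, -0.42), 3.19))) /
              sqrt(oracle_ar2_variance(c(1.30, -0.42), 3.19)), 0.1)
})

test_that("simulated readings clip to the display range and are flagged", {
  t <- 0:60
  bg <- glucose_trace(t, rep(340, length(t)), period = 1)
  spec <- cal_spec("poly0", "poly0")
  hot <- sensor_error_params(kinetics_params(0), cal_params(spec, 1.3, 0),
                             ar_noise_params(numeric(), 0))
  cgm <- simulate_cgm(bg, hot, cgm_period = 5)
  expect_true(all(cgm$glucose_mg_dl == 400))
  expect_true(all(attr(cgm, "saturated")))
})

test_that("parameter JSON round-trips exactly", {
  p <- sensor_error_params(
    kinetics_params(3.78),
    cal_params(cal_spec("poly2", "poly0"), c(0.95, 0.004, 0), 6.35),
    ar_noise_params(c(1.30, -0.42), 3.19))
  f <- withr::local_tempfile(fileext = ".json")
  write_params_json(p, f)
  p2 <- read_params_json(f)
  expect_equal(p2$kinetics$tau, 3.78)
  expect_equal(p2$cal$a_coeffs, c(0.95, 0.004, 0))
  expect_equal(p2$noise$alpha, c(1.30, -0.42))
  expect_equal(p2$noise$sigma, 3.19)
})
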