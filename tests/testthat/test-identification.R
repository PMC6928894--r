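noiseless_pairs <- function(seed = 2, tau = 6, a_coeffs = c(0.92, 0.03, -0.002),
                            b_coeffs = 5, spec = cal_spec("poly2", "poly0")) {
  tiny_sensor(seed = seed, sigma = 0, tau = tau, a_coeffs = a_coeffs,
              b_coeffs = b_coeffs, spec = spec, session_locked = TRUE)
}

test_that("model predictions reproduce the reference under the identity model", {
  sens <- noiseless_pairs(tau = 0, a_coeffs = c(1, 0, 0), b_coeffs = 0)
  pred <- predict_igs(0, cal_params(cal_spec("poly2", "poly0"), c(1, 0, 0), 0),
                      sens$pairs)
  expect_equal(pred, sens$pairs$reference, tolerance = 1e-12)
})

test_that("constant-input predictions match the gain/offset arithmetic", {
  # constant BG 100 through gain 0.95, offset 7.30 gives 102.3 mg/dL
  t <- seq(0, 1440)
  profile <- list(grid_times = t, values = rep(100, length(t)),
                  excluded_intervals = NULL)
  cgm <- glucose_trace(seq(0, 1440, 5), rep(100, 289), period = 5)
  pairs <- match_cgm(profile, cgm)
  pred <- predict_igs(3.1, cal_params(cal_spec("poly0", "poly0"), 0.95, 7.30),
                      pairs)
  expect_equal(pred, rep(102.3, length(pairs$times)))
})

test_that("discretised predictions agree with continuous convolution quadrature", {
  t <- 0:360
  slope <- 0.1
  bg_fun <- function(s) 100 + slope * s
  profile <- list(grid_times = t, values = bg_fun(t), excluded_intervals = NULL)
  cgm_t <- seq(0, 360, 5)
  pairs <- match_cgm(profile, glucose_trace(cgm_t, bg_fun(cgm_t), period = 5))
  tau <- 10
  pred <- predict_igs(tau, cal_params(cal_spec("poly0", "poly0"), 1, 0), pairs)
  oracle <- oracle_ig_quadrature(bg_fun, 0, pairs$times, tau)
  expect_lt(max(abs(pred - oracle)), 0.1)
})

test_that("nonlinear least squares recovers noiseless generating parameters", {
  sens <- noiseless_pairs()
  fit <- fit_step1(sens$pairs, cal_spec("poly2", "poly0"))
  expect_true(fit$converged)
  truth <- c(6, 0.92, 0.03, -0.002, 5)
  expect_equal(unname(fit$theta), truth, tolerance = 1e-3)
  expect_lt(fit$rss / length(sens$pairs$times), 1e-6)
})

test_that("an identity sensor fits exactly with zero residual", {
  sens <- noiseless_pairs(tau = 0, a_coeffs = c(1, 0, 0), b_coeffs = 0)
  fit <- fit_step1(sens$pairs, cal_spec("poly2", "poly0"))
  expect_lt(fit$rss, 1e-10)
})

test_that("too few pairs are rejected", {
  sens <- noiseless_pairs()
  short <- sens$pairs
  keep <- 1:4
  short$times <- short$times[keep]; short$reference <- short$reference[keep]
  short$cgm <- short$cgm[keep]; short$segment_ids <- short$segment_ids[keep]
  expect_error(fit_step1(short, cal_spec("poly2", "poly0")), "at least")
})

test_that("reflection-coefficient mapping round-trips the stationary region", {
  set.seed(4)
  for (q in 1:4) {
    for (rep in 1:20) {
      k <- runif(q, -0.95, 0.95)
      alpha <- cgmerr:::reflection_to_ar(k)
      expect_true(ar_is_stationary(alpha))
      expect_equal(cgmerr:::ar_to_reflection(alpha), k, tolerance = 1e-10)
    }
  }
  # q = 2 image is the open stationarity triangle
  a <- cgmerr:::reflection_to_ar(c(0.99, -0.99))
  expect_true(a[1] + a[2] < 1 && a[2] - a[1] < 1 && abs(a[2]) < 1)
})

test_that("forward-backward AR fitting is consistent", {
  v1 <- simulate_ar_noise(ar_noise_params(0.5, 1), 1e4, seed = 5)
  f1 <- fit_ar(v1, 1)
  expect_lt(abs(f1$alpha - 0.5), 0.02)
  w <- simulate_ar_noise(ar_noise_params(numeric(), 1), 1e4, seed = 6)
  f0 <- fit_ar(w, 2)
  expect_true(all(abs(f0$alpha) < 2 / sqrt(1e4) * 2))
  al <- c(1.30, -0.42)
  v2 <- simulate_ar_noise(ar_noise_params(al, 3.19), 1e4, seed = 7)
  f2 <- fit_ar(v2, 2)
  expect_true(all(abs(f2$alpha - al) < 0.03))
  expect_lt(abs(f2$sigma - 3.19) / 3.19, 0.05)
  # segments are independent: a segment shorter than q+1 contributes nothing
  expect_error(fit_ar(list(rnorm(5)), 2), "pooled")
})

test_that("whitening an AR(2) residual stream leaves white noise", {
  al <- c(1.30, -0.42)
  segs <- lapply(1:3, function(i)
    simulate_ar_noise(ar_noise_params(al, 3.19), 2000, seed = 30 + i))
  wh <- whiten_residuals(segs)
  expect_equal(wh$alpha, al, tolerance = 0.05)
  n <- length(unlist(wh$whitened))
  expect_equal(wh$n, n)
  expect_equal(n, sum(lengths(segs)) - 2L * length(segs))
  ac <- acf(unlist(wh$whitened), lag.max = 5, plot = FALSE)$acf[-1]
  expect_true(all(abs(ac) < 2 / sqrt(n)))
  # white input: whitening coefficients near zero, output nearly the input
  wsegs <- list(simulate_ar_noise(ar_noise_params(numeric(), 1), 3000, seed = 40))
  whw <- whiten_residuals(wsegs)
  expect_true(all(abs(whw$alpha) < 0.05))
  expect_warning(whiten_residuals(c(segs, list(c(1, 2)))), "shorter than 3")
})

test_that("the information criterion follows its defining arithmetic", {
  expect_equal(compute_bic(100, 100, 0), log(100))
  expect_equal(compute_bic(400, 100, 3), 100 * log(4) + 4 * log(100))
  n <- 250; rss <- 1234
  expect_equal(compute_bic(2 * rss, n, 3) - compute_bic(rss, n, 3), n * log(2))
  z <- compute_bic(0, 50, 2)
  expect_identical(as.numeric(z), -Inf)
  expect_true(attr(z, "degenerate"))
  expect_error(compute_bic(10, 3, 5), "n > n_params")
})

test_that("BIC selects the generating AR order", {
  al <- c(1.30, -0.42)
  v <- simulate_ar_noise(ar_noise_params(al, 3.19), 5000, seed = 8)
  sel <- select_ar_order(list(v), q_max = 10)
  expect_equal(sel$order, 2L)
  expect_length(sel$bic, 10L)
  # orders beyond the data are skipped
  sel2 <- select_ar_order(list(v[1:45]), q_max = 10)
  expect_true(max(as.integer(names(sel2$bic))) <= 4L)
})

test_that("two-step identification recovers a noiseless sensor exactly", {
  sens <- noiseless_pairs()
  fit <- suppressWarnings(two_step_identify(sens$pairs, cal_spec("poly2", "poly0")))
  expect_equal(unname(fit$theta), c(6, 0.92, 0.03, -0.002, 5), tolerance = 1e-3)
  expect_lt(fit$params$noise$sigma, 0.01)
})

test_that("two-step identification is close to truth under realistic noise", {
  sens <- tiny_sensor(seed = 55)
  fit <- two_step_identify(sens$pairs, cal_spec("poly2", "poly0"))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates["tau"] - 3.78), 3)
  expect_lt(abs(fit$estimates["alpha1"] - 1.30), 0.15)
  expect_lt(abs(fit$estimates["sigma"] - 3.19), 0.5)
  expect_true(all(c("tau", "a0", "b0", "alpha1", "alpha2", "sigma") %in%
                    names(fit$cv_of_estimates)))
  expect_true(ar_is_stationary(fit$params$noise$alpha))
})

test_that("single-step identification attains the zero-noise optimum", {
  sens <- noiseless_pairs()
  ts <- suppressWarnings(two_step_identify(sens$pairs, cal_spec("poly2", "poly0")))
  ss <- suppressWarnings(single_step_identify(sens$pairs, cal_spec("poly2", "poly0"),
                                              two_step = ts))
  expect_equal(unname(ss$theta), c(6, 0.92, 0.03, -0.002, 5), tolerance = 1e-3)
  expect_lt(ss$rss_whitened, 1e-4)
})

test_that("single-step optimum never exceeds the two-step whitened RSS", {
  for (s in c(12, 13)) {
    sens <- tiny_sensor(seed = s)
    ts <- two_step_identify(sens$pairs, cal_spec("poly2", "poly0"))
    ss <- single_step_identify(sens$pairs, cal_spec("poly2", "poly0"),
                               two_step = ts)
    expect_lte(ss$objective, ts$rss_whitened + 1e-6)
    expect_true(ar_is_stationary(ss$params$noise$alpha))
  }
})

test_that("fit comparison reports RSS differences and agreement", {
  sens <- list(tiny_sensor(seed = 61), tiny_sensor(seed = 62),
               tiny_sensor(seed = 63))
  ts <- lapply(sens, function(s) two_step_identify(s$pairs, cal_spec("poly2", "poly0")))
  ss <- lapply(seq_along(sens), function(i)
    single_step_identify(sens[[i]]$pairs, cal_spec("poly2", "poly0"),
                         two_step = ts[[i]]))
  one <- compare_fits(ts[[1]], ss[[1]])
  expect_lte(one$rss_diff, 1e-6)
  expect_gt(one$rmse_a, 0)
  # identical fits: zero difference, perfect correlation
  self <- compare_cohort(ts, ts)
  expect_true(all(self$rss_diff == 0))
  expect_true(all(self$correlations == 1, na.rm = TRUE))
  both <- compare_cohort(ts, ss)
  expect_equal(both$frac_improved, 1)
  # the sign test is the exact binomial
  expect_equal(both$sign_test$p.value,
               binom.test(sum(both$rss_diff < 0), sum(both$rss_diff != 0))$p.value)
  expect_error(compare_fits(ts[[1]], ss[[2]]), "same pairs")
})
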