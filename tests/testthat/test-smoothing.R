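ref_session <- function(seed = 1, cv = 0.02, by = 15,
                        fun = function(t) 140 + 60 * sin(2 * pi * (t - 480) / 500)) {
  t <- seq(480, 1200, by = by)
  truth <- fun(t)
  set.seed(seed)
  reference_samples(t, truth + rnorm(length(t), 0, cv * truth), cv = cv)
}

test_that("reconstruction is exact on noise-free linear data for any gamma", {
  t <- seq(480, 1200, by = 15)
  rs <- reference_samples(t, 100 + 0.05 * t)
  for (g in c(1e-3, 1, 1e4, NULL)) {
    p <- smooth_reference(rs, gamma = g)
    expect_lt(max(abs(p$values - (100 + 0.05 * p$grid_times))), 1e-6)
  }
})

test_that("the large-gamma limit is the weighted least-squares line", {
  rs <- ref_session(seed = 3)
  p <- smooth_reference(rs, gamma = 1e10)
  w <- 1 / (rs$cv * rs$values)^2
  fit <- lm(rs$values ~ rs$times, weights = w)
  pred <- unname(cbind(1, p$grid_times) %*% coef(fit))
  expect_lt(max(abs(p$values - pred)), 0.05)
})

test_that("likelihood-tuned smoothing beats linear interpolation of noisy samples", {
  fun <- function(t) 140 + 60 * sin(2 * pi * (t - 480) / 500)
  grid <- seq(480, 1200)
  rmse <- sapply(seq_len(100), function(s) {
    rs <- ref_session(seed = s)
    p <- smooth_reference(rs)
    c(smooth = sqrt(mean((p$values - fun(grid))^2)),
      interp = sqrt(mean((approx(rs$times, rs$values, xout = grid)$y -
                            fun(grid))^2)))
  })
  expect_lt(mean(rmse["smooth", ]), mean(rmse["interp", ]))
})

test_that("roughness of the reconstruction is non-increasing in gamma", {
  rs <- ref_session(seed = 7)
  rough <- sapply(10^seq(-2, 6), function(g) {
    p <- smooth_reference(rs, gamma = g)
    sum(diff(p$values, differences = 2)^2)
  })
  expect_true(all(diff(rough) <= 1e-8))
})

test_that("reconstruction approaches interpolation as the assay noise vanishes", {
  rs <- ref_session(seed = 5, cv = 1e-4)
  p <- smooth_reference(rs)
  at_ref <- p$values[match(round(rs$times), p$grid_times)]
  expect_lt(max(abs(at_ref - rs$values)), 0.5)
})

test_that("sessions with fewer than four samples are skipped with a warning", {
  rs <- reference_samples(c(0, 15, 30), c(100, 110, 120))
  expect_warning(p <- smooth_reference(rs), "fewer than 4")
  expect_length(p$values, 0)
})

test_that("gaps longer than the threshold are masked", {
  expect_equal(nrow(mask_gaps(reference_samples(seq(0, 150, 15), rep(100, 11)))), 0)
  rs <- reference_samples(c(0, 15, 40, 55), c(100, 101, 102, 103))
  g <- mask_gaps(rs)
  expect_equal(unname(g), matrix(c(15, 40), 1))
  single <- reference_samples(5, 100)
  expect_equal(nrow(mask_gaps(single)), 0)
})

test_that("pair matching honours the 30-s rule, gap exclusion and idempotence", {
  profile <- list(grid_times = 0:120, values = 100 + (0:120) / 10,
                  excluded_intervals = NULL)
  cgm <- glucose_trace(seq(0, 120, 5), rep(100, 25), period = 5)
  m <- match_cgm(profile, cgm)
  expect_length(m$times, 25)
  expect_equal(m$reference, 100 + m$times / 10)
  expect_equal(unique(m$segment_ids), 1L)
  # a sample 45 s away from the nearest covered grid point is dropped
  prof2 <- list(grid_times = c(0:10, seq(11.75, 20.75, 1)),
                values = rep(100, 21), excluded_intervals = NULL)
  cgm2 <- glucose_trace(c(5, 11), c(100, 100))
  m2 <- match_cgm(prof2, cgm2)
  expect_equal(m2$times, 5)
  # samples inside an excluded gap interval are dropped, splitting segments
  prof3 <- list(grid_times = 0:120, values = rep(100, 121),
                excluded_intervals = matrix(c(20, 45), 1))
  m3 <- match_cgm(prof3, cgm)
  expect_false(any(m3$times > 20 & m3$times < 45))
  expect_equal(max(m3$segment_ids), 2L)
  # deterministic and idempotent
  m3b <- match_cgm(prof3, cgm)
  expect_identical(m3$times, m3b$times)
  expect_identical(m3$segment_ids, m3b$segment_ids)
})

test_that("matched segments carry their 1-min reference series", {
  sens <- tiny_sensor(seed = 21)
  p <- sens$pairs
  expect_length(p$ref_segments, max(p$segment_ids))
  for (s in seq_along(p$ref_segments)) {
    seg <- p$ref_segments[[s]]
    expect_equal(diff(seg$times), rep(1, length(seg$times) - 1))
    ii <- p$segment_ids == s
    expect_true(min(seg$times) <= min(p$times[ii]))
    expect_true(max(seg$times) >= max(p$times[ii]))
  }
})
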