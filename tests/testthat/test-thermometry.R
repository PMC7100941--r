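# Ratiometric thermometry: channel interpolation, calibration, pulse
# averaging, temperature conversion, ROI peak.

test_that("the generator rejects invalid pulse parameters", {
  expect_error(generate_thermo_stack(1, sigma_um = 0), "sigma")
  expect_error(generate_thermo_stack(1, decay_s = -1), "decay")
  expect_error(generate_thermo_stack(1, slope_per_C = 0), "slope")
  expect_error(generate_thermo_stack(-0.1), "amplitude")
})

test_that("zero amplitude yields a constant ratio field", {
  ts <- generate_thermo_stack(0, n_pulses = 2, noise_sd = 0,
                              img_px = c(41, 41), seed = 1L)
  i440 <- interpolate_insensitive(ts$I440_start, ts$I440_end, ts$timestamps)
  rat <- ratio_stack(ts$I490, i440)
  expect_lt(max(abs(rat[[1]] - rat[[length(rat)]])), 1e-12)
  expect_equal(max(ts$true_fac), 0)
})

test_that("peak ratio change equals amplitude times slope at the centre", {
  ts <- generate_thermo_stack(1.5, n_pulses = 1, noise_sd = 0,
                              drift_frac = 0, seed = 1L)
  i440 <- interpolate_insensitive(ts$I440_start, ts$I440_end, ts$timestamps)
  rat <- ratio_stack(ts$I490, i440)
  ctr <- ts$center_px
  peak <- max(vapply(rat, function(m) m[ctr[2], ctr[1]], 0))
  expect_equal(peak - ts$R0, 1.5 * ts$slope_per_C, tolerance = 1e-6)
})

test_that("the transient decays below 5% of peak within three time constants", {
  ts <- generate_thermo_stack(1, n_pulses = 1, decay_s = 2.5,
                              pulse_period_s = 9, noise_sd = 0,
                              img_px = c(41, 41), seed = 1L)
  fac <- ts$true_fac
  on_idx <- which(ts$timestamps >= ts$onsets[1])[1]
  after3 <- which(ts$timestamps >= ts$onsets[1] + 3 * 2.5)[1]
  expect_lt(fac[after3], 0.05 * max(fac))
})

test_that("channel interpolation is linear in time", {
  a <- matrix(100, 5, 5); b <- matrix(200, 5, 5)
  out <- interpolate_insensitive(a, b, c(0, 0.5, 1))
  expect_equal(out[[1]], a)
  expect_equal(out[[2]], matrix(150, 5, 5))
  expect_equal(out[[3]], b)
  expect_error(interpolate_insensitive(NULL, b, 0:1), "endpoint")
  # a linearly drifting field is reproduced exactly at every frame
  ts <- generate_thermo_stack(0, n_pulses = 2, noise_sd = 0,
                              img_px = c(21, 21), seed = 1L)
  i440 <- interpolate_insensitive(ts$I440_start, ts$I440_end, ts$timestamps)
  mid <- length(i440) %/% 2
  drift <- 1 + 0.05 * ts$timestamps[mid] / max(ts$timestamps)
  expect_equal(i440[[mid]], matrix(500 * drift, 21, 21), tolerance = 1e-9)
})

test_that("calibration averages the pre and post slopes", {
  mk <- function(slope) data.frame(temp_C = 23:26,
                                   ratio = 1.5 + slope * (0:3))
  cal <- calibrate_thermometry(mk(0.010), mk(0.012))
  expect_equal(cal$slope_per_C, 0.011)
  expect_equal(cal$residual_pre, 0, tolerance = 1e-12)
  expect_error(calibrate_thermometry(data.frame(temp_C = 23, ratio = 1.5)),
               "2 temperature set points")
  nonmono <- data.frame(temp_C = 23:26, ratio = c(1.5, 1.9, 1.4, 1.8))
  expect_warning(calibrate_thermometry(nonmono), "nonlinear")
})

test_that("pulse alignment averages identical pulses to themselves", {
  # fast decay so successive pulses are truly identical (no residual tail)
  ts <- generate_thermo_stack(0.8, n_pulses = 3, noise_sd = 0,
                              drift_frac = 0, decay_s = 0.25,
                              img_px = c(41, 41), seed = 1L)
  al <- align_average_pulses(ts$I490, ts$timestamps, ts$onsets)
  one <- align_average_pulses(ts$I490, ts$timestamps, ts$onsets[1])
  expect_equal(al$n_pulses, 3)
  expect_equal(one$n_pulses, 1)
  i_pk <- which.min(abs(al$t_rel - 0.5))
  expect_equal(al$mean_stack[[i_pk]], one$mean_stack[[i_pk]],
               tolerance = 1e-6)
  expect_error(align_average_pulses(ts$I490, ts$timestamps, c(10, 11)),
               "overlap")
})

test_that("averaging n pulses shrinks noise about sqrt(n)-fold", {
  set.seed(5)
  n <- 25
  ts <- seq(0, n * 4, by = 0.25)
  onsets <- 2 + (0:(n - 1)) * 4
  sigma <- 1
  stack <- lapply(ts, function(t) matrix(rnorm(16, 0, sigma), 4, 4))
  al <- align_average_pulses(stack, ts, onsets, window = c(-0.5, 3))
  resid <- unlist(al$mean_stack)
  expect_equal(stats::sd(resid), sigma / 5, tolerance = 0.2)
})

test_that("ratio changes convert to temperature by the calibrated slope", {
  cal <- calibrate_thermometry(data.frame(temp_C = 23:26,
                                          ratio = 1.5 + 0.01 * (0:3)))
  base <- matrix(1.5, 9, 9)
  stack <- c(replicate(3, base, simplify = FALSE),
             list(base + 0.015), list(base - 0.005))
  t_rel <- c(-0.3, -0.2, -0.1, 0.1, 0.2)
  out <- delta_ratio_to_temperature(stack, t_rel, cal)
  expect_equal(max(abs(out$dT[[1]])), 0)
  expect_equal(out$dT[[4]][5, 5], 1.5)           # 0.015 / 0.01
  expect_equal(out$dT[[5]][5, 5], -0.5)          # ratio drop -> negative dT
  expect_error(delta_ratio_to_temperature(stack, t_rel + 10, cal), "pre-stimulus")
})

test_that("the ROI mean matches the analytic disk average of a Gaussian", {
  px_um <- 37.4 / 60
  H <- 201
  sig <- 100
  xs <- ((1:H) - 101) * px_um
  field <- 2 * exp(-outer(xs^2, xs^2, `+`) / (2 * sig^2))
  pk <- peak_temperature(list(field), roi_diameter_px = 60,
                         center = c(101, 101))
  expect_equal(pk$series, gaussian_disk_mean(2, sig, 37.4),
               tolerance = 0.02)
  # uniform field: ROI mean equals the field value
  uni <- peak_temperature(list(matrix(2, 101, 101)), 60, center = c(51, 51))
  expect_equal(uni$series, 2)
  # off-centre ROI sees less of the Gaussian
  off <- peak_temperature(list(field), 60, center = c(141, 101))
  expect_lt(off$series, pk$series)
  expect_error(peak_temperature(list(field), 60, center = c(10, 10)),
               "ROI exceeds")
})

test_that("end-to-end recovery is within 2% and linear in amplitude", {
  peaks <- vapply(c(0.4, 0.8, 1.2), function(A) {
    ts <- generate_thermo_stack(A, n_pulses = 6, seed = 7L)
    res <- analyze_thermometry(ts)
    # oracle: identical alignment applied to the true amplitude factor,
    # times the ROI mean of the true Gaussian shape
    al <- align_average_pulses(lapply(ts$true_fac, function(f)
      matrix(f, 1, 1)), ts$timestamps, ts$onsets)
    fac <- vapply(al$mean_stack, function(m) m[1, 1], 0)
    base <- mean(utils::tail(fac[al$t_rel < 0], 3))
    H <- nrow(ts$true_shape); W <- ncol(ts$true_shape)
    roi <- outer(((1:H) - ts$center_px[2])^2,
                 ((1:W) - ts$center_px[1])^2, `+`) <= 30^2
    truth <- (max(fac) - base) * mean(ts$true_shape[roi])
    expect_lt(abs(res$peak_dT - truth) / truth, 0.02)
    res$peak_dT
  }, 0)
  fit <- stats::lm(peaks ~ c(0.4, 0.8, 1.2))
  expect_gt(summary(fit)$r.squared, 0.999)
})
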