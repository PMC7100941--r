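# Calibrations, subpixel registration, stage-motion integration, targeting.

test_that("stage calibration recovers scale and axis inversion", {
  # object moves -10 px when the stage moves +0.1 mm: 0.01 mm/px, x inverted
  px <- rbind(c(0, 0), c(-10, 0), c(0, -10), c(-10, -10))
  mm <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(0.1, 0.1))
  cal <- calibrate_stage(px, mm)
  expect_equal(cal$M, diag(c(-0.01, -0.01)), tolerance = 1e-12)
  expect_equal(cal$residual, 0, tolerance = 1e-12)
  expect_error(calibrate_stage(px[1:2, ], mm[1:2, ]), "at least 3")
  expect_error(calibrate_stage(rbind(c(0, 0), c(1, 0), c(2, 0)),
                               rbind(c(0, 0), c(0.1, 0), c(0.2, 0))),
               "collinear")
})

test_that("galvo calibration recovers a known affine map", {
  th <- 5 * pi / 180
  M <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) / 0.02  # px per V
  set.seed(1)
  volts <- matrix(runif(12, -1, 1), ncol = 2)
  px <- volts %*% t(M) + matrix(c(256, 256), 6, 2, byrow = TRUE)
  g <- calibrate_galvo(volts, px)
  expect_lt(max(abs(g$volt_to_px$M - M)), 1e-6)
  # identity mapping: commanded voltage equals pixel coordinates
  gi <- calibrate_galvo(volts, volts)
  expect_equal(apply_calibration(gi$px_to_volt, c(0.3, -0.2)),
               c(0.3, -0.2), tolerance = 1e-9)
  # noisy clicks leave a residual comparable to the click noise
  set.seed(2)
  reps <- replicate(40, {
    v <- matrix(runif(20, -1, 1), ncol = 2)
    p <- v %*% t(M) + matrix(rnorm(20, 0, 1), ncol = 2)
    calibrate_galvo(v, p)$volt_to_px$residual
  })
  expect_equal(mean(reps), sqrt(2), tolerance = 0.25)  # 2-d rms of sd 1
})

test_that("subpixel shifts are recovered within 0.05 px", {
  for (sh in list(c(0, 0), c(3.25, -1.5), c(0.1, 0))) {
    sf <- shifted_frames(sh)
    es <- estimate_shift(sf$a, sf$b)
    expect_lt(max(abs(es$shift - sf$true_image_shift)), 0.05)
  }
  # against the independent brute-force upsampled-correlation oracle
  sf <- shifted_frames(c(4.62, 2.11))
  es <- estimate_shift(sf$a, sf$b)
  oracle <- oracle_shift(sf$a, sf$b, center = round(es$shift))
  expect_lt(max(abs(es$shift - oracle)), 0.05)
  expect_lt(max(abs(es$shift - sf$true_image_shift)), 0.05)
})

test_that("identical and textureless frames behave as defined", {
  sf <- shifted_frames(c(0, 0))
  expect_equal(estimate_shift(sf$a, sf$a)$shift, c(0, 0))
  flat <- estimate_shift(matrix(0.5, 64, 64), matrix(0.5, 64, 64))
  expect_equal(flat$shift, c(0, 0))
  expect_true(flat$low_confidence)
})

test_that("masked registration ignores the worm region", {
  sf <- shifted_frames(c(2.4, -3.6), noise_sd = 0.008)
  m <- edge_region_mask(dim(sf$a))
  es <- estimate_shift(sf$a, sf$b, mask = m)
  expect_lt(max(abs(es$shift - sf$true_image_shift)), 0.05)
})

test_that("stage integration is exact for constant drift and zero shifts", {
  n <- 50
  mk_shifts <- function(dx, dy) list(
    lag1 = rbind(c(NA, NA), matrix(rep(c(dx, dy), n - 1), ncol = 2,
                                   byrow = TRUE)),
    lag2 = rbind(matrix(NA, 2, 2),
                 matrix(rep(c(2 * dx, 2 * dy), n - 2), ncol = 2,
                        byrow = TRUE)),
    lag3 = rbind(matrix(NA, 3, 2),
                 matrix(rep(c(3 * dx, 3 * dy), n - 3), ncol = 2,
                        byrow = TRUE)))
  cal <- simple_calibration(0.01)
  tr <- integrate_stage_motion(mk_shifts(0.5, -0.25), c(1, 2), cal)
  expect_equal(tr$x_mm, 1 - 0.01 * 0.5 * (0:(n - 1)), tolerance = 1e-12)
  expect_equal(tr$y_mm, 2 + 0.01 * 0.25 * (0:(n - 1)), tolerance = 1e-12)
  tr0 <- integrate_stage_motion(mk_shifts(0, 0), c(1, 2), cal)
  expect_true(all(tr0$x_mm == 1) && all(tr0$y_mm == 2))
})

test_that("lag averaging reduces accumulated noise versus lag-1 only", {
  set.seed(4)
  n <- 200
  reps <- replicate(60, {
    e1 <- rnorm(n); e2 <- rnorm(n); e3 <- rnorm(n)
    s1 <- cbind(e1, 0); s1[1, ] <- NA
    s2 <- cbind(2 * 0 + e2, 0); s2[1:2, ] <- NA
    s3 <- cbind(e3, 0); s3[1:3, ] <- NA
    cal <- simple_calibration(1)
    full <- integrate_stage_motion(list(lag1 = s1, lag2 = s2, lag3 = s3),
                                   c(0, 0), cal)
    only1 <- integrate_stage_motion(list(lag1 = s1), c(0, 0), cal)
    c(full$x_mm[n]^2, only1$x_mm[n]^2)
  })
  expect_lt(mean(reps[1, ]), mean(reps[2, ]))
})

test_that("world conversion composes with the stage position", {
  cal <- simple_calibration(0.0125)
  p <- c(10, -4)
  expect_equal(to_world(p, c(0, 0), cal), p * 0.0125)
  w1 <- to_world(p, c(0, 0), cal)
  w2 <- to_world(p, c(1, 0), cal)
  expect_equal(w2 - w1, c(1, 0))
  # round trip world -> pixel -> world
  w <- c(3.21, -1.07)
  expect_equal(to_world(to_pixel(w, c(0.4, 0.2), cal), c(0.4, 0.2), cal),
               w, tolerance = 1e-9)
})

test_that("head targeting picks the anterior-fifth midpoint", {
  pts <- cbind(seq(0, 80, length.out = 49), rep(0, 49))  # 1 mm at 80 px
  sk <- structure(list(points = pts, length_px = 80, complex = FALSE,
                       oriented = TRUE), class = "worm_skeleton")
  t1 <- target_head(sk, 0.2, speed_mm_s = 0.2, frame_rate = 20)
  expect_equal(t1$target_px, c(8, 0), tolerance = 1e-6)  # 0.1 of the body
  expect_equal(t1$lag_error_mm, 0.01)                    # 0.2 mm/s / 20 Hz
  expect_equal(target_head(sk, 1.0)$target_px, c(40, 0),
               tolerance = 1e-6)                          # body midpoint
  sk$oriented <- FALSE
  expect_error(target_head(sk, 0.2), "oriented")
})

test_that("closed-loop targeting error shrinks with frame rate and speed", {
  err_for <- function(fps, speed) {
    sch <- locomotion_schedule(data.frame(state = "forward",
                                          duration_s = 10,
                                          speed_mm_s = speed),
                               frame_rate = fps, seed = 12L)
    tr <- generate_track(sch)
    n <- nrow(tr$frames)
    d <- vapply(2:n, function(i) {
      sk <- structure(list(points = tr$skeletons[, , i - 1],
                           length_px = 1, complex = FALSE, oriented = TRUE),
                      class = "worm_skeleton")
      tgt <- target_head(sk, 0.2)$target_px
      dense <- resample_polyline(tr$skeletons[, , i], 401)
      sqrt(sum((tgt - dense[41, ])^2))   # distance to the true point
    }, 0)
    mean(d)
  }
  e_base <- err_for(20, 0.2)
  expect_lt(e_base, err_for(10, 0.2))   # slower sampling -> worse
  expect_lt(e_base, err_for(20, 0.4))   # faster worm -> worse
})
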