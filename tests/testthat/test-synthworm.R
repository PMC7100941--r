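# Synthetic locomotion generator: ground truth and rendering.

test_that("schedules validate their segments", {
  expect_error(locomotion_schedule(data.frame(state = "moonwalk",
                                              duration_s = 1)),
               "segment 1 has invalid state 'moonwalk'")
  expect_error(locomotion_schedule(data.frame(state = "forward",
                                              duration_s = 0)),
               "non-positive duration")
  sch <- locomotion_schedule(data.frame(state = "pause", duration_s = 2,
                                        speed_mm_s = 0.3))
  expect_equal(sch$segments$speed_mm_s, 0)  # pause forces speed 0
})

test_that("schedules round-trip through YAML", {
  sch <- escape_schedule(seed = 11L)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_schedule(sch, p)
  sch2 <- read_schedule(p)
  expect_equal(sch2$segments$state, sch$segments$state)
  expect_equal(sch2$seed, sch$seed)
  expect_equal(sch2$frame_rate, sch$frame_rate)
})

test_that("an all-pause schedule produces zero centroid displacement", {
  sch <- locomotion_schedule(data.frame(state = "pause", duration_s = 10),
                             seed = 2L)
  tr <- generate_track(sch)
  expect_equal(max(abs(diff(tr$frames$centroid_x_mm))), 0)
  expect_equal(max(abs(diff(tr$frames$centroid_y_mm))), 0)
  expect_equal(unique(tr$frames$phase_vel_cyc_s), 0)
})

test_that("true phase advances f x duration during forward crawling", {
  sch <- locomotion_schedule(data.frame(state = "forward", duration_s = 10,
                                        freq_cyc_s = 0.5), seed = 1L)
  tr <- generate_track(sch)
  expect_equal(diff(range(tr$frames$phase_cycles)), 5.0)  # 0.5 * 10 s
  # displacement per frame = speed / frame_rate
  d <- sqrt(diff(tr$frames$centroid_x_mm)^2 + diff(tr$frames$centroid_y_mm)^2)
  expect_equal(d, rep(0.2 / 20, length(d)), tolerance = 1e-12)
})

test_that("turns collapse the head-tail distance below half its crawl value", {
  sch <- escape_schedule(pre_s = 4, rev_s = 2, turn_s = 1.5, post_s = 5,
                         seed = 3L)
  tr <- generate_track(sch)
  fr <- tr$frames
  fwd_ht <- mean(fr$headtail_mm[fr$state == "forward"])
  expect_lt(min(fr$headtail_mm[fr$state == "turn"]), 0.5 * fwd_ht)
  # reversal inverts phase progression and centroid heading
  expect_true(all(fr$phase_vel_cyc_s[fr$state == "reverse"] < 0))
  expect_true(all(fr$phase_vel_cyc_s[fr$state == "forward"] > 0))
})

test_that("ground truth is deterministic and co-indexed", {
  sch <- escape_schedule(seed = 9L, pre_s = 2, post_s = 2)
  tr1 <- generate_track(sch)
  tr2 <- generate_track(sch)
  expect_identical(tr1$frames, tr2$frames)
  expect_identical(tr1$skeletons, tr2$skeletons)
  expect_equal(dim(tr1$skeletons)[3], nrow(tr1$frames))
})

test_that("differentiating true phase recovers true phase velocity", {
  segs <- data.frame(state = c("forward", "reverse"),
                     duration_s = c(6, 6), freq_cyc_s = 0.5)
  tr <- generate_track(locomotion_schedule(segs, seed = 4L))
  fps <- 20
  num <- diff(tr$frames$phase_cycles) * fps
  truthv <- tr$frames$phase_vel_cyc_s[-1]
  interior <- abs(seq_along(num) - 6 * fps) > 2  # away from the transition
  expect_lt(max(abs(num[interior] - truthv[interior]) /
                abs(truthv[interior])), 0.01)
})

test_that("noiseless renders threshold back to the exact body mask", {
  sch <- locomotion_schedule(data.frame(state = "forward", duration_s = 1),
                             seed = 3L)
  tr <- generate_track(sch)
  opt <- render_optics(noise_sd = 0, texture_amp = 0)
  rec <- render_frames(tr, opt)
  body <- true_mask(rec, 5)
  got <- rec$stack[[5]] < (opt$bg_level + opt$worm_level) / 2
  expect_equal(iou(got, body), 1)
})

test_that("the rendered background shifts with the stage", {
  sf <- shifted_frames(c(3, -2))
  # brute-force integer cross-correlation over a border patch
  patch_a <- sf$a[1:30, ]
  best <- c(NA, NA); best_cc <- -Inf
  for (dy in -5:5) for (dx in -5:5) {
    rows <- (1:30) + dy + 5; cols_a <- 11:(ncol(sf$a) - 10)
    pb <- sf$b[rows + 0, cols_a + dx]
    pa <- sf$a[(1:30) + 5, cols_a]
    cc <- stats::cor(as.vector(pa), as.vector(pb))
    if (cc > best_cc) { best_cc <- cc; best <- c(dx, dy) }
  }
  expect_equal(best, sf$true_image_shift)
})

test_that("looped turn frames render with an interior background hole", {
  rec <- loop_recording()
  tr <- rec$truth
  i <- which(tr$frames$turn_bend > 0.99)[8]
  body <- true_mask(rec, i)
  comp <- EBImage::bwlabel(!body)
  border <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1],
                     comp[, ncol(comp)]))
  expect_gt(length(setdiff(seq_len(max(comp)), c(0, border))), 0)
})

test_that("frames leaving the field of view are flagged, not dropped", {
  sch <- locomotion_schedule(data.frame(state = "forward", duration_s = 10,
                                        speed_mm_s = 0.3), seed = 6L)
  tr <- generate_track(sch, stage_gain = 0)   # stage does not track
  rec <- render_frames(tr, render_optics(img_px = c(96, 96)))
  expect_gt(length(rec$flagged_frames), 0)
  expect_equal(length(rec$stack), nrow(tr$frames))
})

test_that("recordings round-trip through the on-disk layout", {
  rec <- fwd_recording()
  d <- withr::local_tempdir()
  sub <- rec
  sub$stack <- rec$stack[1:10]
  sub$timestamps <- rec$timestamps[1:10]
  sub$truth$frames <- rec$truth$frames[1:10, ]
  sub$stage_reported <- rec$stage_reported[1:10, ]
  sub$stimuli <- data.frame(time_s = 0.1, frame = 3, target_x_mm = 0,
                            target_y_mm = 0, current_mA = 75,
                            duration_ms = 100, lens_mm = 75)
  write_recording(sub, d)
  back <- read_recording(d)
  expect_equal(length(back$stack), 10)
  expect_equal(back$frame_rate, rec$frame_rate)
  expect_equal(max(abs(back$stack[[4]] - sub$stack[[4]])), 0,
               tolerance = 1 / 65535)
  expect_equal(back$stimuli$frame, 3)
})
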