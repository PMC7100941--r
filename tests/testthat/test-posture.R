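# Posture: midline extraction, eigenworm decomposition, posture-space
# repair, head-tail correction.

test_that("a straight rod yields a straight, full-length midline", {
  rod <- matrix(FALSE, 40, 120)
  rod[18:22, 11:110] <- TRUE
  sk <- midline_simple(rod)
  expect_false(sk$complex)
  expect_equal(sk$length_px, 100, tolerance = 2 / 100)
  pts <- sk$points
  expect_lt(sqrt(mean((pts[, 2] - 20)^2)), 0.5)
})

test_that("midlines track the generating curve within one pixel", {
  rec <- fwd_recording()
  ea <- expected_worm_area(rec)
  for (i in c(12, 48, 90)) {
    sf <- segment_frame(rec$stack[[i]], ea)
    sk <- midline_simple(sf$mask)
    expect_false(sk$complex)
    err <- rmse_curves(sk$points, true_skeleton_px(rec, i))
    expect_lt(err, 1)
    # endpoints within 2 px of the true tips
    tp <- true_skeleton_px(rec, i)
    ends <- rbind(sk$points[1, ], sk$points[nrow(sk$points), ])
    d <- c(min(sqrt(rowSums((ends - tp[rep(1, 2), ])^2))),
           min(sqrt(rowSums((ends - tp[rep(49, 2), ])^2))))
    expect_lt(max(d), 2)
  }
})

test_that("looped masks raise the complex flag instead of a skeleton", {
  lrec <- loop_recording()
  i <- which(lrec$truth$frames$turn_bend > 0.99)[8]
  mask <- true_mask(lrec, i)
  kept <- fill_holes_keep_loops(mask)
  sk <- midline_simple(kept$mask)
  expect_true(sk$complex)
  expect_null(sk$points)
})

test_that("complex-frame flagging finds turns and injected faults", {
  rec <- fwd_recording()
  ea <- expected_worm_area(rec)
  idx <- seq(1, 160, by = 1)
  skels <- lapply(idx, function(i)
    midline_simple(segment_frame(rec$stack[[i]], ea)$mask))
  expect_length(flag_complex_frames(skels), 0)  # pure forward: no coils
  # corrupt one frame's skeleton length
  skels[[80]]$length_px <- skels[[80]]$length_px * 0.5
  expect_true(80 %in% flag_complex_frames(skels))
  # scripted deep turns are flagged via the loop-hole criterion
  lrec <- loop_recording()
  tr <- lrec$truth
  turn_core <- which(tr$frames$turn_bend > 0.99)
  lsk <- lapply(seq_len(dim(tr$skeletons)[3]), function(i) {
    m <- fill_holes_keep_loops(true_mask(lrec, i))
    sk <- midline_simple(m$mask)
    sk
  })
  flags <- flag_complex_frames(lsk)
  expect_true(all(turn_core %in% flags))
})

test_that("the eigenworm basis is orthonormal and two modes carry crawling", {
  sch <- locomotion_schedule(data.frame(state = "forward", duration_s = 8),
                             seed = 3L)
  tr <- generate_track(sch)
  b <- build_eigenbasis(tr$skeletons)
  expect_lt(max(abs(crossprod(b$modes) - diag(4))), 1e-10)
  expect_gte(sum(b$var_explained[1:2]), 0.90)
  # oracle: direct eigendecomposition of the angle covariance
  A <- t(apply(tr$skeletons, 3, function(s) tangent_angles(s)))
  A <- A - rowMeans(A)
  A <- sweep(A, 2, colMeans(A))
  ev <- eigen(crossprod(A), symmetric = TRUE)
  for (k in 1:2)
    expect_equal(abs(sum(b$modes[, k] * ev$vectors[, k])), 1,
                 tolerance = 1e-8)
  # K = 4 reconstruction of a sample profile within 10% RMS
  pr <- project_modes(tr$skeletons[, , 33], b)
  expect_lt(pr$residual_rms, 0.10)
  expect_error(build_eigenbasis(tr$skeletons[, , 1:50]),
               "at least 100")
})

test_that("mode projection is an orthonormal inner product", {
  basis <- reference_eigenbasis()
  # skeleton equal to the mean profile -> all modes zero
  th0 <- basis$mean_profile
  sk0 <- angles_to_midline(th0, 80)
  expect_equal(max(abs(project_modes(sk0, basis)$a)), 0, tolerance = 1e-9)
  # mean + 2 x mode1 -> a = (2, 0, 0, 0)
  sk1 <- angles_to_midline(th0 + 2 * basis$modes[, 1], 80)
  expect_equal(project_modes(sk1, basis)$a, c(2, 0, 0, 0),
               tolerance = 1e-6)
  # head-tail flip changes the coefficients
  skel <- fwd_recording()$truth$skeletons[, , 25]
  a_fwd <- project_modes(skel, basis)$a
  a_flip <- project_modes(skel[rev(1:49), ], basis)$a
  expect_gt(max(abs(a_fwd - a_flip)), 0.1)
  # oracle: explicit reversal computation of the flipped profile
  th <- tangent_angles(skel[rev(1:49), ])
  v <- th - mean(th) - basis$mean_profile
  expect_equal(a_flip, as.numeric(crossprod(basis$modes, v)),
               tolerance = 1e-10)
})

test_that("unoriented skeletons cannot be projected", {
  sk <- midline_simple(true_mask(fwd_recording(), 10))
  expect_error(project_modes(sk, reference_eigenbasis()), "oriented")
})

test_that("posture-space interpolation is near-identity without gaps and accurate across them", {
  fps <- 20
  tt <- seq(0, 20, by = 1 / fps)
  modes <- cbind(cos(2 * pi * 0.5 * tt), -sin(2 * pi * 0.5 * tt), 0, 0)
  ip <- interpolate_complex(modes, integer(0), fps)
  expect_lt(max(abs(ip$modes - modes)), 1e-3)
  # 5-frame gap on the (a1, a2) circle: phase error < 0.05 cycles
  gap <- 200:204
  m2 <- modes; m2[gap, ] <- NA
  ip2 <- interpolate_complex(m2, gap, fps)
  phi_t <- unwrap_phase(atan2(-modes[, 2], modes[, 1])) / (2 * pi)
  phi_i <- unwrap_phase(atan2(-ip2$modes[, 2], ip2$modes[, 1])) / (2 * pi)
  expect_lt(max(abs(phi_i[gap] - phi_t[gap])), 0.05)
  expect_true(all(ip2$reconstructed[gap]))
  # gaps at the recording boundary, or longer than the cap, become missing
  m3 <- modes; m3[1:5, ] <- NA
  expect_true(all(interpolate_complex(m3, 1:5, fps)$missing[1:5]))
  long <- 100:160
  m4 <- modes; m4[long, ] <- NA
  expect_true(all(interpolate_complex(m4, long, fps)$missing[long]))
})

test_that("head-tail correction restores injected flips from one anchor", {
  rec <- escape_recording()
  tr <- rec$truth
  n <- dim(tr$skeletons)[3]
  skels <- lapply(seq_len(n), function(i)
    structure(list(points = true_skeleton_px(rec, i),
                   length_px = 80, complex = FALSE, oriented = FALSE),
              class = "worm_skeleton"))
  # inject flips on three scattered runs
  set.seed(7)
  flipped_truth <- rep(FALSE, n)
  for (s in sample(10:(n - 10), 3)) {
    run <- s:min(n, s + 6)
    flipped_truth[run] <- !flipped_truth[run]
  }
  bad <- skels
  for (i in which(flipped_truth))
    bad[[i]]$points <- bad[[i]]$points[rev(1:49), , drop = FALSE]
  ev <- rec$stimuli
  st <- c(tr$frames$stage_x_mm[ev$frame], tr$frames$stage_y_mm[ev$frame])
  tgt <- world_to_frame_px(c(ev$target_x_mm, ev$target_y_mm), st,
                           rec$optics, rec$pixel_size_mm)
  fixed <- correct_head_tail(bad, data.frame(frame = ev$frame,
                                             x = tgt[1], y = tgt[2]))
  heads_ok <- vapply(seq_len(n), function(i)
    sqrt(sum((fixed$skeletons[[i]]$points[1, ] -
              skels[[i]]$points[1, ])^2)) < 1e-9, TRUE)
  expect_equal(mean(heads_ok), 1)  # 100% restored
  # consistent series: orientation unchanged
  again <- correct_head_tail(fixed$skeletons,
                             data.frame(frame = ev$frame,
                                        x = tgt[1], y = tgt[2]))
  expect_false(any(again$flipped, na.rm = TRUE))
})

test_that("ambiguous anchors request annotation instead of guessing", {
  pts <- cbind(seq(10, 58), rep(20, 49))
  sk <- list(structure(list(points = pts, length_px = 48, complex = FALSE,
                            oriented = FALSE), class = "worm_skeleton"))
  mid <- colMeans(pts[c(1, 49), ])
  expect_error(correct_head_tail(sk, data.frame(frame = 1, x = mid[1],
                                                y = mid[2])),
               "annotate")
  expect_error(correct_head_tail(sk, NULL), "anchor")
})

test_that("the (a1, a2) trajectory winds at the undulation frequency", {
  sch <- locomotion_schedule(data.frame(state = "forward", duration_s = 10,
                                        freq_cyc_s = 0.5), seed = 8L)
  tr <- generate_track(sch)
  pr <- project_series(tr$skeletons, reference_eigenbasis())
  phi <- unwrap_phase(atan2(-pr$modes[, 2], pr$modes[, 1])) / (2 * pi)
  rate <- (phi[length(phi)] - phi[1]) / 10
  expect_equal(rate, 0.5, tolerance = 0.02)
  # arc length conserved across frames
  lens <- apply(tr$skeletons, 3, polyline_length)
  expect_lt(diff(range(lens)) / stats::median(lens), 0.05)
})
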