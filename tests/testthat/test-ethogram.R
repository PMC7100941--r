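# Behavioral flagging, minimum bout duration, population summaries.

test_that("state flags follow the printed thresholds and precedence", {
  # |omega| = 0.015 with normal posture -> pause
  expect_equal(flag_states(0.015, 1, avg_headtail = 1), "pause")
  # head-tail distance at 0.4 x average -> turn regardless of omega
  expect_equal(flag_states(0.8, 0.4, avg_headtail = 1), "turn")
  expect_equal(flag_states(NA, 0.4, avg_headtail = 1), "turn")
  # omega = +0.8 with normal posture -> forward
  expect_equal(flag_states(0.8, 1, avg_headtail = 1), "forward")
  expect_equal(flag_states(-0.8, 1, avg_headtail = 1), "reverse")
  expect_equal(flag_states(NA, 1, avg_headtail = 1), "missing")
})

test_that("the average head-tail distance is robust to the turns", {
  ht <- c(rep(1, 90), rep(0.3, 10))   # 10% of frames deep in a turn
  st <- flag_states(rep(0.5, 100), ht)
  expect_equal(unname(table(st)["turn"]), 10L)
})

test_that("minimum-duration enforcement matches the worked examples", {
  fps <- 20
  # F(10) R(3) F(10): 0.15 s < 0.25 s -> all forward
  s1 <- rep(c("forward", "reverse", "forward"), c(10, 3, 10))
  e1 <- enforce_min_duration(s1, fps)
  expect_true(all(e1$states == "forward"))
  # F(10) R(6) F(10): 0.30 s >= 0.25 s -> reversal retained
  s2 <- rep(c("forward", "reverse", "forward"), c(10, 6, 10))
  e2 <- enforce_min_duration(s2, fps)
  expect_equal(e2$states, s2)
  # alternating 2-frame chatter collapses to a single state
  s3 <- rep(rep(c("forward", "reverse"), 10), each = 2)
  e3 <- enforce_min_duration(s3, fps)
  expect_equal(length(unique(e3$states)), 1)
})

test_that("enforcement is idempotent, label-preserving, and tiles the record", {
  set.seed(9)
  for (r in 1:20) {
    raw <- sample(c("forward", "reverse", "pause", "turn", "missing"),
                  120, replace = TRUE,
                  prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
    e <- enforce_min_duration(raw, 20)
    seg <- e$segments
    interior <- seg[-c(1, nrow(seg)), , drop = FALSE]
    if (nrow(interior)) expect_true(all(interior$duration_s >= 0.25))
    expect_true(all(e$states %in% unique(raw)))
    expect_equal(sum(seg$n_frames), 120)
    e2 <- enforce_min_duration(e$states, 20)
    expect_identical(e2$states, e$states)
  }
})

test_that("escape distance is zero at the stimulus and metric afterwards", {
  tt <- seq(0, 10, by = 0.05)
  # straight retreat at 0.2 mm/s
  ctr <- cbind(0.2 * tt, 0 * tt)
  d <- escape_distance(ctr, tt, 2)
  expect_equal(d$distance_mm[d$t_rel_s == 0], 0)
  expect_equal(d$distance_mm[d$t_rel_s == 5], 1.0)  # 0.2 mm/s x 5 s
  expect_true(all(is.na(d$distance_mm[d$t_rel_s < 0])))
  # closed loop returns to ~0 but never below
  th <- 2 * pi * tt / 10
  loop <- cbind(cos(th) - 1, sin(th))
  dl <- escape_distance(loop, tt, 0)
  expect_true(all(dl$distance_mm >= 0, na.rm = TRUE))
  expect_lt(dl$distance_mm[length(tt)], 1e-9)
  expect_error(escape_distance(ctr, tt, 99), "outside")
})

test_that("population alignment computes fractions and SEM correctly", {
  fps <- 20
  tt <- seq(0, 30, by = 1 / fps)
  om_values <- c(0.42, 0.48, 0.55, 0.61)
  animals <- lapply(om_values, function(v)
    list(time_s = tt, states = rep("forward", length(tt)),
         omega = rep(v, length(tt)),
         centroid_mm = cbind(0.1 * tt, 0), events = 10))
  ps <- align_to_stimulus(animals, window = c(-2, 10), step = 0.05)
  g <- ps$grid
  expect_true(all(abs(g$frac_forward - 1) < 1e-12))
  expect_true(all(g$frac_reverse == 0 & g$frac_pause == 0 &
                  g$frac_turn == 0))
  sums <- g$frac_forward + g$frac_reverse + g$frac_pause + g$frac_turn
  expect_lt(max(abs(sums - 1)), 1e-12)
  # SEM at n = 4 equals the hand computation
  expect_equal(unique(round(g$mean_omega, 12)), mean(om_values))
  expect_equal(g$sem_omega[1], stats::sd(om_values) / sqrt(4),
               tolerance = 1e-12)
  expect_true(all(g$n_omega == 4))
  # escape distance starts at zero
  expect_lt(abs(g$mean_escape_mm[which.min(abs(g$t_rel_s))]), 1e-9)
  expect_error(align_to_stimulus(animals, window = c(5, 5)), "window")
  expect_error(align_to_stimulus(list()), "empty")
})

test_that("the escape motif orders the reversal and turn peaks", {
  cohort <- lapply(1:8, function(j) {
    sch <- escape_schedule(pre_s = 6, rev_s = 2 + 0.1 * j, turn_s = 1.5,
                           post_s = 10, seed = 100L + j)
    tr <- script_stimuli(generate_track(sch), 6)
    ana <- analyze_skeleton_series(tr$skeletons, 20)
    k <- ana$kinematics
    list(time_s = k$time_s, states = ana$ethogram$states,
         omega = k$omega_cyc_s,
         centroid_mm = cbind(tr$frames$centroid_x_mm,
                             tr$frames$centroid_y_mm),
         events = tr$stimuli$time_s)
  })
  ps <- align_to_stimulus(cohort, window = c(-3, 12), step = 0.05)
  g <- ps$grid
  post <- g$t_rel_s > 0
  t_rev <- g$t_rel_s[post][which.max(g$frac_reverse[post])]
  t_turn <- g$t_rel_s[post][which.max(g$frac_turn[post])]
  expect_lt(t_rev, t_turn)  # reversal peak precedes the turn peak
  expect_gt(max(g$frac_reverse[post]), 0.9)
  .fix$escape_cohort <- cohort
})

test_that("populations split by initial state and by state at a time", {
  fps <- 20
  tt <- seq(0, 30, by = 1 / fps)
  mk <- function(pre_state) list(
    time_s = tt,
    states = ifelse(tt < 10, pre_state, "reverse"),
    omega = rep(0.5, length(tt)),
    centroid_mm = cbind(0.1 * tt, 0), events = 10)
  animals <- c(lapply(1:5, function(i) mk("forward")),
               lapply(1:4, function(i) mk("pause")))
  ps <- align_to_stimulus(animals, window = c(-3, 10), step = 0.05)
  sp <- split_by_initial_state(ps, c(-2, 0))
  expect_equal(sp$forward$n, 5)
  expect_equal(sp$pause$n, 4)
  # a uniformly forward pre-window gives a single nonempty partition
  uni <- align_to_stimulus(lapply(1:3, function(i) mk("forward")),
                           window = c(-3, 10), step = 0.05)
  spu <- split_by_initial_state(uni, c(-2, 0))
  expect_equal(spu$forward$n, 3)
  expect_false("pause" %in% setdiff(names(spu), "partition"))
  # double-stimulus rule: state at +2 s after the first stimulus
  dbl <- c(lapply(1:3, function(i) mk("forward")),             # reversing at 12
           lapply(1:2, function(i) {
             a <- mk("forward"); a$states[tt >= 11.5] <- "pause"; a
           }))
  pd <- align_to_stimulus(dbl, window = c(-1, 10), step = 0.05)
  sd2 <- split_by_initial_state(pd, 2)
  expect_equal(sd2$reverse$n, 3)  # still reversing -> LONG
  expect_equal(sd2$pause$n, 2)    # paused -> SHORT
})
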