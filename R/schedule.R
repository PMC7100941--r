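# Locomotion schedules: scripted state sequences driving the synthetic worm.

.worm_states <- c("forward", "reverse", "pause", "turn")

#' Build a locomotion schedule
#'
#' A schedule is an ordered list of behavioral segments (state, duration,
#' crawl speed, undulation frequency and amplitude) plus the acquisition
#' parameters of the simulated recording. It drives [generate_track()].
#'
#' @param segments data.frame with columns `state` (one of `"forward"`,
#'   `"reverse"`, `"pause"`, `"turn"`), `duration_s`, `speed_mm_s`,
#'   `freq_cyc_s`, `amp_rad`. Missing kinematic columns are filled with the
#'   defaults below.
#' @param frame_rate acquisition rate in Hz (recordings here are 15-20 Hz;
#'   default 20 so that 5 frames are exactly 0.25 s).
#' @param pixel_size_mm camera scale, mm per pixel.
#' @param worm_length_mm body arc length (adult worms are about 1 mm).
#' @param seed integer seed; the whole simulation is deterministic given the
#'   schedule and this seed.
#' @param speed_mm_s,freq_cyc_s,amp_rad defaults used where `segments` omits
#'   the column: crawl speed 0.2 mm/s, undulation 0.5 cycles/s, bend
#'   amplitude 0.55 rad.
#' @param wavelength_frac undulation wavelength as a fraction of body length
#'   (default 0.9).
#' @param turn_depth_rad total body bend at the apex of an omega turn
#'   (radians along the whole body). The default 5.8 collapses the head-tail
#'   distance well below half its crawling value without self-intersection;
#'   values above ~6.9 produce a self-occluding loop.
#' @param turn_ramp_s time to ramp the turn bend in and out.
#' @param trans_rate_cap maximum rate of change of the true phase velocity
#'   at state transitions (cycles/s^2): the worm decelerates into and
#'   accelerates out of each transition at this rate rather than switching
#'   instantaneously.
#' @param heading_wander_rad smooth per-frame heading jitter (sd of the
#'   random-walk increment, rad); 0 disables wander.
#' @return object of class `locomotion_schedule`.
#' @export
locomotion_schedule <- function(segments,
                                frame_rate = 20,
                                pixel_size_mm = 0.0125,
                                worm_length_mm = 1,
                                seed = 1L,
                                speed_mm_s = 0.2,
                                freq_cyc_s = 0.5,
                                amp_rad = 0.55,
                                wavelength_frac = 0.9,
                                turn_depth_rad = 5.8,
                                turn_ramp_s = 0.15,
                                heading_wander_rad = 0.0,
                                trans_rate_cap = 1.6) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (!"state" %in% names(segments))
    stop("schedule segments need a 'state' column")
  if (!"duration_s" %in% names(segments))
    stop("schedule segments need a 'duration_s' column")
  bad <- which(!segments$state %in% .worm_states)
  if (length(bad))
    stop(sprintf("segment %d has invalid state '%s' (must be one of %s)",
                 bad[1], segments$state[bad[1]],
                 paste(.worm_states, collapse = ", ")))
  if (any(!is.finite(segments$duration_s)) || any(segments$duration_s <= 0))
    stop(sprintf("segment %d has non-positive duration",
                 which(segments$duration_s <= 0)[1]))
  if (is.null(segments$speed_mm_s)) segments$speed_mm_s <- speed_mm_s
  if (is.null(segments$freq_cyc_s)) segments$freq_cyc_s <- freq_cyc_s
  if (is.null(segments$amp_rad))    segments$amp_rad    <- amp_rad
  segments$speed_mm_s[segments$state %in% c("pause", "turn")] <- 0
  segments$freq_cyc_s[segments$state == "pause"] <- 0
  stopifnot_scalar(frame_rate, "frame_rate")
  stopifnot_scalar(pixel_size_mm, "pixel_size_mm")
  stopifnot_scalar(worm_length_mm, "worm_length_mm")
  out <- list(segments = segments,
              frame_rate = frame_rate,
              pixel_size_mm = pixel_size_mm,
              worm_length_mm = worm_length_mm,
              seed = as.integer(seed),
              wavelength_frac = wavelength_frac,
              turn_depth_rad = turn_depth_rad,
              turn_ramp_s = turn_ramp_s,
              heading_wander_rad = heading_wander_rad,
              trans_rate_cap = trans_rate_cap)
  class(out) <- "locomotion_schedule"
  out
}

#' @export
print.locomotion_schedule <- function(x, ...) {
  cat(sprintf("Locomotion schedule: %d segments, %.1f s total, %g Hz, seed %d\n",
              nrow(x$segments), sum(x$segments$duration_s), x$frame_rate,
              x$seed))
  print(x$segments)
  invisible(x)
}

#' Scripted escape-motif schedule
#'
#' Convenience constructor for the stereotyped escape sequence: baseline
#' forward crawling, then reversal, deep omega turn, and resumed forward
#' motion after the (virtual) stimulus.
#'
#' @param pre_s forward crawling before the stimulus.
#' @param rev_s,turn_s,post_s durations of the reversal, omega turn, and
#'   resumed forward segment.
#' @param ... passed to [locomotion_schedule()].
#' @return `locomotion_schedule`; the stimulus is implied at the end of the
#'   first segment (use [script_stimuli()] to attach the event).
#' @export
escape_schedule <- function(pre_s = 20, rev_s = 4, turn_s = 1.5,
                            post_s = 30, ...) {
  segs <- data.frame(
    state = c("forward", "reverse", "turn", "forward"),
    duration_s = c(pre_s, rev_s, turn_s, post_s))
  locomotion_schedule(segs, ...)
}

#' Scripted cohort schedule with randomized bouts and an escape motif
#'
#' Builds one recording's schedule for a synthetic cohort study: randomized
#' forward/pause/reverse bouts before and after a stimulus-locked escape
#' motif (reverse, omega turn, resumed forward crawling) placed at
#' `stim_time_s`. Bout durations and undulation frequencies vary across
#' seeds; all segments respect the 0.25 s minimum bout convention by a wide
#' margin.
#'
#' @param duration_s total recording length (s).
#' @param seed per-recording seed (also seeds [generate_track()]).
#' @param stim_time_s time of the scripted stimulus/escape motif.
#' @param frame_rate Hz.
#' @param ... passed to [locomotion_schedule()].
#' @return `locomotion_schedule`.
#' @export
random_schedule <- function(duration_s = 120, seed = 1L, stim_time_s = 60,
                            frame_rate = 20, ...) {
  set.seed(seed)
  fill <- function(total) {
    segs <- list()
    left <- total
    state <- sample(c("forward", "pause"), 1, prob = c(0.7, 0.3))
    while (left > 0) {
      d <- min(left, stats::runif(1, 2, 8))
      if (left - d < 1) d <- left
      segs[[length(segs) + 1L]] <- data.frame(
        state = state, duration_s = d,
        speed_mm_s = stats::runif(1, 0.12, 0.25),
        freq_cyc_s = stats::runif(1, 0.4, 0.6),
        amp_rad = stats::runif(1, 0.5, 0.6))
      left <- left - d
      state <- if (state == "forward")
        sample(c("pause", "reverse"), 1, prob = c(0.7, 0.3)) else "forward"
    }
    do.call(rbind, segs)
  }
  pre <- fill(stim_time_s)
  motif <- data.frame(
    state = c("reverse", "turn", "forward"),
    duration_s = c(stats::runif(1, 2, 5), stats::runif(1, 1, 2),
                   stats::runif(1, 6, 10)),
    speed_mm_s = c(stats::runif(1, 0.2, 0.3), 0, stats::runif(1, 0.2, 0.3)),
    freq_cyc_s = stats::runif(3, 0.5, 0.7),
    amp_rad = 0.55)
  post <- fill(max(1, duration_s - stim_time_s - sum(motif$duration_s)))
  locomotion_schedule(rbind(pre, motif, post), frame_rate = frame_rate,
                      seed = seed, ...)
}

#' Write / read a schedule as YAML
#' @param schedule `locomotion_schedule`.
#' @param path file path.
#' @return `read_schedule` returns a `locomotion_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  x <- unclass(schedule)
  x$segments <- as.list(as.data.frame(x$segments))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- yaml::read_yaml(path)
  segs <- as.data.frame(x$segments, stringsAsFactors = FALSE)
  x$segments <- NULL
  do.call(locomotion_schedule, c(list(segments = segs), x))
}
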