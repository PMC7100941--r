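# Four-state behavioral flagging, minimum bout duration, and
# stimulus-aligned population summaries.

.etho_states <- c("forward", "reverse", "pause", "turn", "missing")

#' Flag per-frame behavioral states
#'
#' Precedence: a frame is a turn when the head-tail distance falls below
#' `turn_frac` of the average head-tail distance (posture evidence dominates
#' during coils, where omega is unreliable); otherwise a frame with removed
#' or undefined phase velocity is missing; otherwise a pause when
#' |omega| < `pause_thr` (cycles/s); otherwise forward or reverse by the
#' sign of omega.
#'
#' The average head-tail distance is the per-recording median over frames
#' that are not turn candidates (robust to the turns themselves): a first
#' median over all frames marks candidates, the final median excludes them.
#'
#' @param omega cleaned phase velocity (cycles/s; NA = removed).
#' @param headtail head-tail distances (any consistent unit); NA allowed.
#' @param avg_headtail override for the average head-tail distance
#'   (default: robust per-recording median as above).
#' @param pause_thr pause threshold (0.02 cycles/s).
#' @param turn_frac turn threshold as a fraction of the average head-tail
#'   distance (0.5).
#' @param turn_candidates optional logical vector of extra turn evidence
#'   (e.g. preserved loop holes on complex frames).
#' @return character vector of states.
#' @export
flag_states <- function(omega, headtail, avg_headtail = NULL,
                        pause_thr = 0.02, turn_frac = 0.5,
                        turn_candidates = NULL) {
  n <- length(omega)
  stopifnot(length(headtail) == n)
  if (is.null(avg_headtail)) {
    m0 <- stats::median(headtail, na.rm = TRUE)
    keep <- !is.na(headtail) & headtail >= turn_frac * m0
    avg_headtail <- stats::median(headtail[keep], na.rm = TRUE)
  }
  turn <- !is.na(headtail) & headtail < turn_frac * avg_headtail
  if (!is.null(turn_candidates)) turn <- turn | turn_candidates
  state <- rep("missing", n)
  state[turn] <- "turn"
  ok <- !turn & is.finite(omega)
  state[ok & abs(omega) < pause_thr] <- "pause"
  state[ok & abs(omega) >= pause_thr & omega > 0] <- "forward"
  state[ok & abs(omega) >= pause_thr & omega < 0] <- "reverse"
  state
}

# run-length segments of a state vector
state_segments <- function(states, frame_rate = NULL) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(state = r$values, start = starts, end = ends,
                    n_frames = r$lengths, stringsAsFactors = FALSE)
  if (!is.null(frame_rate)) {
    seg$t_start <- (seg$start - 1L) / frame_rate
    seg$t_end <- (seg$end - 1L) / frame_rate
    seg$duration_s <- seg$n_frames / frame_rate
  }
  seg
}

#' Enforce the minimum behavioral-segment duration
#'
#' Fluctuations shorter than `min_s` (0.25 s) are assigned the state of the
#' surrounding behavior: iteratively, shortest sub-minimum segment first
#' (ties to the earliest), a short segment is reassigned to the neighboring
#' state when both neighbors agree, and merged into the longer neighbor
#' when they differ (ties into the preceding segment); a short segment at
#' the recording boundary merges into its only neighbor. The procedure is
#' deterministic and repeats until no segment is shorter than the minimum
#' (a recording consisting of a single segment is left as is).
#'
#' @param states raw per-frame states.
#' @param frame_rate Hz.
#' @param min_s minimum segment duration (s); the frame count is
#'   `round(min_s * frame_rate)` (5 frames at 20 Hz, 4 at 15 Hz).
#' @return object of class `ethogram`: `$states`, `$segments` (state,
#'   start/end frame, duration), `$frame_rate`.
#' @export
enforce_min_duration <- function(states, frame_rate, min_s = 0.25) {
  min_frames <- round(min_s * frame_rate)
  s <- states
  repeat {
    seg <- state_segments(s)
    ns <- nrow(seg)
    if (ns < 2L) break
    short <- which(seg$n_frames < min_frames)
    if (!length(short)) break
    j <- short[order(seg$n_frames[short], seg$start[short])][1]
    new_state <- if (j == 1L) seg$state[2L]
      else if (j == ns) seg$state[ns - 1L]
      else {
        prev <- seg$state[j - 1L]; nxt <- seg$state[j + 1L]
        if (prev == nxt) prev
        else if (seg$n_frames[j - 1L] >= seg$n_frames[j + 1L]) prev
        else nxt
      }
    s[seg$start[j]:seg$end[j]] <- new_state
  }
  structure(list(states = s,
                 segments = state_segments(s, frame_rate),
                 frame_rate = frame_rate),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("Ethogram: %d frames at %g Hz, %d segments\n",
              length(x$states), x$frame_rate, nrow(x$segments)))
  print(table(x$states))
  invisible(x)
}

#' Escape distance from a stimulus event
#'
#' Radial distance between the worm's instantaneous centroid and its
#' centroid at the stimulus time, for t >= the event time.
#'
#' @param centroid_mm T x 2 (smoothed, world mm).
#' @param time_s time stamps.
#' @param event_time_s stimulus time (must lie within the recording).
#' @return data.frame: time_s, t_rel_s, distance_mm (NA before the event).
#' @export
escape_distance <- function(centroid_mm, time_s, event_time_s) {
  if (event_time_s < min(time_s) || event_time_s > max(time_s))
    stop("stimulus event lies outside the recording")
  ref <- c(stats::approx(time_s, centroid_mm[, 1], xout = event_time_s)$y,
           stats::approx(time_s, centroid_mm[, 2], xout = event_time_s)$y)
  d <- sqrt((centroid_mm[, 1] - ref[1])^2 + (centroid_mm[, 2] - ref[2])^2)
  d[time_s < event_time_s] <- NA_real_
  data.frame(time_s = time_s, t_rel_s = time_s - event_time_s,
             distance_mm = d)
}

#' Align per-animal traces to their stimuli and summarize the population
#'
#' Each animal contributes one trace per stimulus event: its state
#' (nearest-frame), phase velocity (linear interpolation) and escape
#' distance are resampled onto a common relative-time grid with the
#' stimulus at t = 0. Population state fractions are computed over
#' non-missing animals, phase velocity and escape distance as
#' mean +/- SEM (sd/sqrt(n)), with n reported per time point, plus
#' pre-stimulus baselines (means over the pre-window).
#'
#' @param animals list; each element a list with `time_s`, `states`,
#'   `omega`, `centroid_mm` (T x 2), `events` (stimulus times, s).
#' @param window c(pre, post) seconds around the stimulus (pre negative).
#' @param step grid step (s).
#' @return object of class `population_summary`: `$grid` data.frame
#'   (t_rel_s, frac_* per state, mean/sem omega, mean/sem escape, n),
#'   `$baseline` (pre-stimulus means), `$traces` (aligned per-trace
#'   matrices: states, omega, escape).
#' @export
align_to_stimulus <- function(animals, window = c(-5, 30), step = 0.05) {
  if (!length(animals)) stop("empty cohort")
  if (window[2] <= window[1]) stop("empty alignment window")
  grid <- seq(window[1], window[2], by = step)
  st_list <- list(); om_list <- list(); di_list <- list()
  for (a in animals) {
    for (ev in a$events) {
      rel <- a$time_s - ev
      idx <- vapply(grid, function(g) which.min(abs(rel - g)), 0L)
      near <- abs(rel[idx] - grid) <= 1.01 * max(step, diff(a$time_s[1:2]))
      stt <- a$states[idx]
      stt[!near] <- NA
      st_list[[length(st_list) + 1L]] <- stt
      om <- rep(NA_real_, length(grid))
      okf <- is.finite(a$omega)
      if (sum(okf) >= 2L)
        om <- stats::approx(rel[okf], a$omega[okf], xout = grid,
                            rule = 1)$y
      om[!near] <- NA
      om_list[[length(om_list) + 1L]] <- om
      ed <- escape_distance(a$centroid_mm, a$time_s, ev)
      di <- stats::approx(ed$t_rel_s[!is.na(ed$distance_mm)],
                          ed$distance_mm[!is.na(ed$distance_mm)],
                          xout = grid, rule = 1)$y
      di[grid < 0] <- NA
      di_list[[length(di_list) + 1L]] <- di
    }
  }
  S <- do.call(rbind, st_list)     # traces x time
  OM <- do.call(rbind, om_list)
  DI <- do.call(rbind, di_list)
  non_missing <- !is.na(S) & S != "missing"
  n_state <- colSums(non_missing)
  fr <- sapply(c("forward", "reverse", "pause", "turn"), function(st)
    colSums(S == st & non_missing, na.rm = TRUE) / pmax(n_state, 1L))
  sem <- function(M) {
    n <- colSums(is.finite(M))
    m <- colMeans(M, na.rm = TRUE)
    s <- apply(M, 2, stats::sd, na.rm = TRUE)
    list(mean = m, sem = s / sqrt(pmax(n, 1L)), n = n)
  }
  om_s <- sem(OM); di_s <- sem(DI)
  grid_df <- data.frame(t_rel_s = grid,
                        frac_forward = fr[, "forward"],
                        frac_reverse = fr[, "reverse"],
                        frac_pause = fr[, "pause"],
                        frac_turn = fr[, "turn"],
                        n_state = n_state,
                        mean_omega = om_s$mean, sem_omega = om_s$sem,
                        n_omega = om_s$n,
                        mean_escape_mm = di_s$mean,
                        sem_escape_mm = di_s$sem, n_escape = di_s$n)
  pre <- grid < 0
  baseline <- data.frame(
    omega = mean(OM[, pre], na.rm = TRUE),
    frac_forward = mean(fr[pre, "forward"]),
    frac_reverse = mean(fr[pre, "reverse"]),
    frac_pause = mean(fr[pre, "pause"]),
    frac_turn = mean(fr[pre, "turn"]))
  structure(list(grid = grid_df, baseline = baseline,
                 traces = list(states = S, omega = OM, escape = DI)),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population summary: %d traces, %d time points (%.2f..%.2f s)\n",
              nrow(x$traces$states), nrow(x$grid), min(x$grid$t_rel_s),
              max(x$grid$t_rel_s)))
  invisible(x)
}

#' Split a population by behavioral state before (or at) a reference time
#'
#' With a length-2 `window`, animals are partitioned by their modal
#' ethogram state inside that relative-time window (e.g. pre-stimulus
#' forward vs pause). With a scalar `window`, they are partitioned by their
#' state at that single time point — the rule used for the double-stimulus
#' short/long-response split (still reversing at +2 s = LONG, paused =
#' SHORT). Empty partitions are reported with n = 0, never dropped.
#'
#' @param summary `population_summary` from [align_to_stimulus()].
#' @param window length-2 relative-time window, or a scalar time.
#' @param states which states define partitions (default all observed).
#' @return named list of per-partition summaries (recomputed over the
#'   partition's traces), plus `$partition` (per-trace label) and `$n`.
#' @export
split_by_initial_state <- function(summary, window = c(-2, 0),
                                   states = NULL) {
  grid <- summary$grid$t_rel_s
  S <- summary$traces$states
  if (length(window) == 2L) {
    cols <- which(grid >= window[1] & grid <= window[2])
    lab <- apply(S[, cols, drop = FALSE], 1, function(r) {
      r <- r[!is.na(r) & r != "missing"]
      if (!length(r)) return(NA_character_)
      names(sort(table(r), decreasing = TRUE))[1]
    })
  } else {
    col <- which.min(abs(grid - window))
    lab <- S[, col]
  }
  if (is.null(states))
    states <- intersect(.etho_states, unique(stats::na.omit(lab)))
  parts <- lapply(states, function(st) {
    rows <- which(!is.na(lab) & lab == st)
    list(n = length(rows),
         rows = rows,
         summary = if (length(rows))
           resummarize_traces(summary, rows) else NULL)
  })
  names(parts) <- states
  c(parts, list(partition = lab))
}

# recompute a population_summary over a subset of traces
resummarize_traces <- function(summary, rows) {
  grid <- summary$grid$t_rel_s
  S <- summary$traces$states[rows, , drop = FALSE]
  OM <- summary$traces$omega[rows, , drop = FALSE]
  DI <- summary$traces$escape[rows, , drop = FALSE]
  non_missing <- !is.na(S) & S != "missing"
  n_state <- colSums(non_missing)
  fr <- sapply(c("forward", "reverse", "pause", "turn"), function(st)
    colSums(S == st & non_missing, na.rm = TRUE) / pmax(n_state, 1L))
  sem <- function(M) {
    n <- colSums(is.finite(M))
    list(mean = colMeans(M, na.rm = TRUE),
         sem = apply(M, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1L)),
         n = n)
  }
  om_s <- sem(OM); di_s <- sem(DI)
  grid_df <- data.frame(t_rel_s = grid,
                        frac_forward = fr[, "forward"],
                        frac_reverse = fr[, "reverse"],
                        frac_pause = fr[, "pause"],
                        frac_turn = fr[, "turn"],
                        n_state = n_state,
                        mean_omega = om_s$mean, sem_omega = om_s$sem,
                        n_omega = om_s$n,
                        mean_escape_mm = di_s$mean,
                        sem_escape_mm = di_s$sem, n_escape = di_s$n)
  structure(list(grid = grid_df, baseline = NULL,
                 traces = list(states = S, omega = OM, escape = DI)),
            class = "population_summary")
}
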