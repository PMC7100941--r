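# Ratiometric fluorescence thermometry: dual-excitation BCECF stacks to
# temperature-change maps and peak time courses.

#' Interpolate the temperature-insensitive channel across the session
#'
#' The 440 nm-excitation channel is acquired only at the start and end of a
#' session; the per-frame estimate is the per-pixel linear interpolation in
#' time between those two endpoint frames.
#'
#' @param start_frame,end_frame H x W matrices (counts).
#' @param timestamps frame times (s).
#' @param t_start,t_end acquisition times of the endpoint frames (default
#'   the first and last timestamps).
#' @return list of H x W matrices, one per timestamp.
#' @export
interpolate_insensitive <- function(start_frame, end_frame, timestamps,
                                    t_start = NULL, t_end = NULL) {
  if (is.null(start_frame) || is.null(end_frame))
    stop("both endpoint frames of the insensitive channel are required")
  t0 <- t_start %||% timestamps[1]
  t1 <- t_end %||% timestamps[length(timestamps)]
  lapply(timestamps, function(t) {
    u <- if (t1 > t0) (t - t0) / (t1 - t0) else 0
    start_frame * (1 - u) + end_frame * u
  })
}

#' Fit the ratio-temperature calibration
#'
#' Ordinary least-squares linear fit of the 490/440 ratio against
#' temperature for each calibration session (before and after laser
#' stimulation), with the two slopes averaged. A large residual (above
#' `warn_frac` of the ratio dynamic range) indicates a nonlinear or
#' nonmonotone calibration and triggers a warning.
#'
#' @param pre,post data.frames with columns `temp_C`, `ratio` (>= 2 set
#'   points each; the study calibrated at 23-26 degrees C).
#' @param warn_frac residual warning threshold.
#' @return object of class `thermo_calibration`: `slope_per_C` (averaged),
#'   `slope_pre`, `slope_post`, `residual_pre`, `residual_post`.
#' @export
calibrate_thermometry <- function(pre, post = NULL, warn_frac = 0.05) {
  fit1 <- function(df, label) {
    if (nrow(df) < 2L)
      stop(sprintf("%s calibration needs at least 2 temperature set points",
                   label))
    f <- stats::lm(ratio ~ temp_C, data = df)
    res <- sqrt(mean(stats::residuals(f)^2))
    rng <- diff(range(df$ratio))
    if (rng > 0 && res > warn_frac * rng)
      warning(sprintf("%s calibration residual %.3g exceeds %g%% of the dynamic range; ratio-temperature relation may be nonlinear",
                      label, res, 100 * warn_frac))
    list(slope = unname(stats::coef(f)[2]), residual = res)
  }
  a <- fit1(pre, "pre")
  b <- if (!is.null(post)) fit1(post, "post") else a
  structure(list(slope_per_C = (a$slope + b$slope) / 2,
                 slope_pre = a$slope, slope_post = b$slope,
                 residual_pre = a$residual, residual_post = b$residual),
            class = "thermo_calibration")
}

#' @export
print.thermo_calibration <- function(x, ...) {
  cat(sprintf("Thermometry calibration: slope %.4g /degC (pre %.4g, post %.4g)\n",
              x$slope_per_C, x$slope_pre, x$slope_post))
  invisible(x)
}

#' Per-frame 490/440 ratio stack
#'
#' @param I490 list of sensitive-channel frames.
#' @param I440_interp list of interpolated insensitive-channel frames.
#' @param dark_offset constant dark offset subtracted from both channels
#'   before the ratio (default 0).
#' @return list of ratio matrices (NA where the 440 estimate is <= 0).
#' @export
ratio_stack <- function(I490, I440_interp, dark_offset = 0) {
  mapply(function(a, b) {
    den <- b - dark_offset
    out <- (a - dark_offset) / den
    out[den <= 0] <- NA_real_
    out
  }, I490, I440_interp, SIMPLIFY = FALSE)
}

#' Align pulse windows in time and average them
#'
#' Extracts a window around each pulse onset on a common relative-time
#' frame grid and averages the windows pixel-wise. Windows that would
#' overlap are rejected by name.
#'
#' @param stack list of frames (e.g. ratio frames).
#' @param timestamps frame times (s).
#' @param onsets pulse onset times (s).
#' @param window c(pre, post) seconds around each onset.
#' @return list: `mean_stack` (list of matrices), `t_rel` (relative times),
#'   `n_pulses`.
#' @export
align_average_pulses <- function(stack, timestamps, onsets,
                                 window = c(-0.25, 3)) {
  if (!length(onsets)) stop("need at least one pulse onset")
  if (length(onsets) > 1L) {
    gaps <- diff(sort(onsets))
    bad <- which(gaps < diff(window))
    if (length(bad))
      stop(sprintf("pulse windows overlap between onsets %.2f s and %.2f s",
                   sort(onsets)[bad[1]], sort(onsets)[bad[1] + 1L]))
  }
  dt <- stats::median(diff(timestamps))
  rel <- seq(ceiling(window[1] / dt), floor(window[2] / dt)) * dt
  acc <- NULL
  n_used <- 0L
  for (on in onsets) {
    idx <- vapply(on + rel, function(tt) which.min(abs(timestamps - tt)), 0L)
    if (max(abs(timestamps[idx] - (on + rel))) > dt) next
    win <- stack[idx]
    if (is.null(acc)) acc <- win
    else acc <- mapply(`+`, acc, win, SIMPLIFY = FALSE)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no pulse window fits inside the recording")
  list(mean_stack = lapply(acc, `/`, n_used), t_rel = rel,
       n_pulses = n_used)
}

#' Convert a pulse-aligned ratio stack to temperature change
#'
#' The ratio change of each frame relative to the mean of 3 pre-stimulus
#' frames is divided by the averaged calibration slope, giving the
#' temperature change above baseline for the full field at every time
#' point.
#'
#' @param mean_stack pulse-aligned ratio frames (from
#'   [align_average_pulses()]).
#' @param t_rel relative times of the frames (s; stimulus at 0).
#' @param cal `thermo_calibration`.
#' @param n_baseline number of pre-stimulus frames averaged (default 3).
#' @return list: `dT` (list of matrices, degC), `t_rel`, `baseline`
#'   (ratio matrix).
#' @export
delta_ratio_to_temperature <- function(mean_stack, t_rel, cal,
                                       n_baseline = 3L) {
  if (cal$slope_per_C == 0) stop("calibration slope is zero")
  pre <- which(t_rel < 0)
  if (length(pre) < n_baseline)
    stop(sprintf("need %d pre-stimulus frames in the window, found %d",
                 n_baseline, length(pre)))
  use <- utils::tail(pre, n_baseline)
  baseline <- Reduce(`+`, mean_stack[use]) / n_baseline
  dT <- lapply(mean_stack, function(fr) (fr - baseline) / cal$slope_per_C)
  list(dT = dT, t_rel = t_rel, baseline = baseline)
}

#' Circular-ROI peak temperature time course
#'
#' Per-frame mean of the temperature-change field over a circular region of
#' interest (default 60 px diameter) centred on the beam; the beam centre
#' defaults to the arg-max of the time-maximum temperature map.
#'
#' @param dT list of temperature-change frames.
#' @param roi_diameter_px ROI diameter (px).
#' @param center c(x, y) beam centre (px); NULL = automatic.
#' @return list: `series` (per-frame ROI mean, degC), `max` (its maximum),
#'   `center`, `roi_diameter_px`.
#' @export
peak_temperature <- function(dT, roi_diameter_px = 60, center = NULL) {
  H <- nrow(dT[[1]]); W <- ncol(dT[[1]])
  if (is.null(center)) {
    # beam centre from the time-maximum map: blur, then take the
    # intensity-weighted centroid of the above-median part, which is robust
    # to pixel noise even when the beam is much wider than the field
    tmax <- EBImage::gblur(Reduce(pmax, dT), sigma = 5)
    w <- pmax(tmax - stats::median(tmax), 0)
    xs <- matrix(1:W, H, W, byrow = TRUE)
    ys <- matrix(1:H, H, W)
    center <- c(sum(w * xs), sum(w * ys)) / sum(w)
  }
  r <- roi_diameter_px / 2
  if (center[1] - r < 0.5 || center[1] + r > W + 0.5 ||
      center[2] - r < 0.5 || center[2] + r > H + 0.5)
    stop("ROI exceeds the field of view")
  roi <- outer(((1:H) - center[2])^2, ((1:W) - center[1])^2, `+`) <= r^2
  series <- vapply(dT, function(fr) mean(fr[roi]), 0)
  list(series = series, max = max(series), center = center,
       roi_diameter_px = roi_diameter_px)
}

#' Full thermometry analysis of a session
#'
#' Chains channel interpolation, ratio computation, calibration, pulse
#' alignment/averaging, baseline-subtracted temperature conversion, and the
#' ROI peak series.
#'
#' @param session a `thermo_stack` (or compatible list).
#' @param roi_diameter_px analysis ROI diameter.
#' @param window pulse window (s).
#' @param center optional beam centre override.
#' @param dark_offset dark offset for the ratio.
#' @return list: `cal`, `dT`, `t_rel`, `peak` (ROI series), `peak_dT`
#'   (scalar max of the ROI mean series), `n_pulses`.
#' @export
analyze_thermometry <- function(session, roi_diameter_px = 60,
                                window = c(-0.25, 3), center = NULL,
                                dark_offset = 0) {
  i440 <- interpolate_insensitive(session$I440_start, session$I440_end,
                                  session$timestamps)
  rat <- ratio_stack(session$I490, i440, dark_offset = dark_offset)
  cal <- calibrate_thermometry(session$cal_pre, session$cal_post)
  al <- align_average_pulses(rat, session$timestamps, session$onsets,
                             window = window)
  dt <- delta_ratio_to_temperature(al$mean_stack, al$t_rel, cal)
  pk <- peak_temperature(dt$dT, roi_diameter_px, center = center)
  list(cal = cal, dT = dt$dT, t_rel = dt$t_rel, peak = pk,
       peak_dT = pk$max, n_pulses = al$n_pulses)
}
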