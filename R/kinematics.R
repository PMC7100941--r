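# Translational velocity (robust spline smoothing + heading sign) and phase
# velocity from eigenworm modes, with spike removal.

#' Robustly smooth a centroid track
#'
#' Penalized-spline smoothing per axis with the smoothing parameter chosen
#' by generalized cross-validation, followed by robustness iterations that
#' down-weight outlier points (Tukey bisquare on the residuals). Reduces
#' high-frequency noise on the derivative without biasing the
#' low-frequency trajectory.
#'
#' @param xy T x 2 raw centroid positions (mm); NA rows are bridged.
#' @param time_s time stamps (default uniform).
#' @param robust_iter number of reweighting iterations.
#' @return T x 2 smoothed positions.
#' @export
smooth_centroid <- function(xy, time_s = NULL, robust_iter = 3L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 10L) stop("need at least 10 frames to smooth a track")
  if (all(is.na(xy))) stop("track is entirely missing")
  t <- time_s %||% seq_len(n)
  out <- xy
  for (j in 1:2) {
    v <- fill_na_linear(xy[, j])
    wts <- rep(1, n)
    fit <- NULL
    for (it in 0:robust_iter) {
      fit <- tryCatch(
        stats::smooth.spline(t, v, w = wts, cv = FALSE, all.knots = TRUE),
        error = function(e) NULL)
      if (is.null(fit)) break
      res <- v - stats::predict(fit, t)$y
      s <- stats::mad(res)
      if (s < 1e-12) break
      u <- res / (4.685 * s)
      wts <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      wts[wts < 1e-6] <- 1e-6
    }
    out[, j] <- if (is.null(fit)) v else stats::predict(fit, t)$y
  }
  out
}

#' Translational speed and signed velocity
#'
#' Speed is the magnitude of the derivative of the smoothed centroid. The
#' sign comes from the angle theta between the centroid movement vector and
#' the worm's orientation (centroid to head): positive (forward) for
#' theta < pi/2, negative (reverse) for theta > pi/2.
#'
#' @param centroid_mm T x 2 smoothed centroid (mm, world).
#' @param head_mm T x 2 head positions (mm, world); NA rows inherit the
#'   previous sign.
#' @param frame_rate Hz.
#' @return data.frame: speed_mm_s, theta_rad, signed_v_mm_s, sign_carried.
#' @export
translational_velocity <- function(centroid_mm, head_mm, frame_rate) {
  n <- nrow(centroid_mm)
  d <- rbind(centroid_mm[2, ] - centroid_mm[1, ],
             diff(centroid_mm)) * frame_rate
  speed <- sqrt(rowSums(d^2))
  hs <- heading_sign(centroid_mm, head_mm)
  data.frame(speed_mm_s = speed, theta_rad = hs$theta,
             signed_v_mm_s = hs$sign * speed, sign_carried = hs$carried)
}

#' Heading sign of centroid movement
#'
#' @param centroid_mm T x 2 centroid positions.
#' @param head_mm T x 2 head positions (same frame, same units).
#' @param eps movement magnitudes below this carry the previous sign
#'   (flagged), avoiding sign chatter at near-zero speed.
#' @return list: `sign` (+1/-1), `theta` (rad in [0, pi]), `carried`
#'   (logical).
#' @export
heading_sign <- function(centroid_mm, head_mm, eps = 1e-9) {
  n <- nrow(centroid_mm)
  mv <- rbind(c(NA, NA), diff(as.matrix(centroid_mm)))
  ov <- as.matrix(head_mm) - as.matrix(centroid_mm)
  dot <- rowSums(mv * ov)
  theta <- acos(pmin(pmax(dot / (sqrt(rowSums(mv^2)) *
                                 sqrt(rowSums(ov^2))), -1), 1))
  sgn <- ifelse(theta < pi / 2, 1, -1)
  carried <- !is.finite(sgn) | sqrt(rowSums(mv^2)) < eps |
    !is.finite(theta)
  s <- 1
  for (i in seq_len(n)) {
    if (carried[i] || is.na(sgn[i])) sgn[i] <- s else s <- sgn[i]
  }
  list(sign = sgn, theta = theta, carried = carried)
}

#' Undulation phase from posture modes
#'
#' Phase is the full-quadrant arctangent `atan2(-a2, a1)`, unwrapped over
#' time and reported in cycles. (The two-quadrant principal value is
#' `tan^-1(-a2/a1)`; the full-quadrant form is required for a continuous
#' phase.) Frames with a1 = a2 = 0 are marked undefined.
#'
#' @param modes T x K mode matrix (uses columns 1 and 2).
#' @param tol both-|a| threshold below which the phase is undefined.
#' @return list: `phi_cycles` (unwrapped), `undefined` (logical).
#' @export
posture_phase <- function(modes, tol = 1e-9) {
  a1 <- modes[, 1]; a2 <- modes[, 2]
  undef <- (!is.finite(a1)) | (!is.finite(a2)) |
    (abs(a1) < tol & abs(a2) < tol)
  phi <- atan2(-a2, a1) / (2 * pi)
  phi[undef] <- NA_real_
  list(phi_cycles = unwrap_phase(phi, period = 1), undefined = undef)
}

#' Phase velocity
#'
#' Time derivative of the unwrapped phase: central differences at interior
#' frames, one-sided at the ends. Positive values correspond to forward
#' undulation, negative to backward.
#'
#' @param phi_cycles unwrapped phase (cycles); NA propagates.
#' @param frame_rate Hz.
#' @return omega (cycles/s), same length.
#' @export
phase_velocity <- function(phi_cycles, frame_rate) {
  n <- length(phi_cycles)
  if (n < 2L) return(rep(NA_real_, n))
  om <- rep(NA_real_, n)
  om[1] <- (phi_cycles[2] - phi_cycles[1]) * frame_rate
  om[n] <- (phi_cycles[n] - phi_cycles[n - 1]) * frame_rate
  if (n > 2L)
    om[2:(n - 1)] <- (phi_cycles[3:n] - phi_cycles[1:(n - 2)]) *
      frame_rate / 2
  om
}

#' Remove physiologically impossible phase-velocity spikes
#'
#' Implements the two-part cleaning rule: (i) frames adjacent to a change in
#' omega exceeding `threshold` are removed (default 0.18 cycles/s per
#' frame; set `units = "per_second"` to read the threshold as cycles/s^2);
#' (ii) peaks in |d omega/dt| above mean + 3 sd (statistics from a
#' reference population when given, else from this recording) are located,
#' and frames within half the peak width before and after each peak are
#' removed. Removals are flagged with their reason.
#'
#' @param omega phase-velocity series (cycles/s).
#' @param frame_rate Hz.
#' @param threshold jump threshold (cycles/s per frame by default).
#' @param units `"per_frame"` (default) or `"per_second"`.
#' @param pop_stats optional list(mean, sd) of |d omega/dt| from a worm
#'   population.
#' @param n_sd peak threshold in standard deviations (default 3).
#' @param min_peak floor on the peak height (cycles/s^2). The 3-sd
#'   statistic scales with the recording's own noise, so on nearly
#'   noiseless data it would flag ordinary fluctuations; peaks must also
#'   reach a physically meaningful size (default: half the jump threshold,
#'   expressed as a rate).
#' @return list: `omega` (cleaned, NA where removed), `removed` (logical),
#'   `reason` (`""`, `"jump"`, `"peak-window"`), `low_quality` (TRUE when
#'   more than half the frames were removed).
#' @export
remove_phase_spikes <- function(omega, frame_rate, threshold = 0.18,
                                units = c("per_frame", "per_second"),
                                pop_stats = NULL, n_sd = 3,
                                min_peak = NULL) {
  units <- match.arg(units)
  n <- length(omega)
  dom <- diff(omega)                       # per-frame change, cycles/s
  jump_thr <- if (units == "per_frame") threshold else threshold / frame_rate
  removed <- rep(FALSE, n)
  reason <- rep("", n)
  jumps <- which(abs(dom) > jump_thr)      # between frames i and i+1
  for (i in jumps) {
    removed[c(i, i + 1L)] <- TRUE
    reason[c(i, i + 1L)] <- "jump"
  }
  # peak pass on |d omega/dt| in cycles/s^2
  domdt <- abs(dom) * frame_rate
  st <- if (!is.null(pop_stats)) pop_stats
        else list(mean = mean(domdt, na.rm = TRUE),
                  sd = stats::sd(domdt, na.rm = TRUE))
  min_peak <- min_peak %||% (jump_thr * frame_rate / 2)
  if (is.finite(st$sd) && st$sd > 0) {
    height <- max(st$mean + n_sd * st$sd, min_peak)
    dd <- domdt
    dd[!is.finite(dd)] <- 0
    pk <- pracma::findpeaks(dd, minpeakheight = height)
    if (!is.null(pk)) {
      for (r in seq_len(nrow(pk))) {
        pos <- pk[r, 2]              # index into diff series
        half <- max(1L, ceiling((pk[r, 4] - pk[r, 3]) / 2))
        lo <- max(1L, pos - half)
        hi <- min(n, pos + 1L + half)
        idx <- lo:hi
        reason[idx][!removed[idx]] <- "peak-window"
        removed[idx] <- TRUE
      }
    }
  }
  removed[!is.finite(omega)] <- TRUE
  reason[!is.finite(omega) & reason == ""] <- "undefined"
  out <- omega
  out[removed] <- NA_real_
  low_q <- mean(removed) > 0.5
  if (low_q)
    warning("more than 50% of frames removed; recording marked low-quality")
  list(omega = out, removed = removed, reason = reason,
       low_quality = low_q)
}
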