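# Synthetic single-worm locomotion: ground-truth tracks and rendered stacks.
#
# The body is a traveling sinusoidal bend along an arc-length-parameterized
# midline: tangent angle psi(s,t) = psi0(t) + A sin(2*pi*s/lambda - 2*pi*phi(t))
# plus, during omega turns, a smoothly ramped constant-curvature coil. The
# first two posture modes of this model form a quadrature pair, which is the
# assumption the eigenworm phase analysis rests on.

#' Generate ground-truth worm locomotion from a schedule
#'
#' Integrates the scripted schedule into per-frame state, centroid, oriented
#' skeleton (head first), undulation phase and phase velocity, plus a
#' simulated tracking-stage trajectory that follows the worm. Deterministic
#' for a fixed schedule (including its seed).
#'
#' @param schedule a [locomotion_schedule()].
#' @param n_points number of skeleton points (default 49).
#' @param stage_gain per-frame fraction by which the stage closes the gap to
#'   the worm centroid (simulated tracking servo).
#' @return object of class `worm_ground_truth`: `$frames` (data.frame with
#'   frame, time_s, state, centroid, phase in cycles, phase velocity in
#'   cycles/s, stage position, heading, head-tail distance), `$skeletons`
#'   (n_points x 2 x n array, mm, head at index 1), `$schedule`, `$stimuli`
#'   (empty until [script_stimuli()]).
#' @export
generate_track <- function(schedule, n_points = 49, stage_gain = 0.25) {
  if (!inherits(schedule, "locomotion_schedule"))
    stop("'schedule' must be a locomotion_schedule")
  segs <- schedule$segments
  fps <- schedule$frame_rate
  dt <- 1 / fps
  L <- schedule$worm_length_mm
  lambda <- schedule$wavelength_frac * L
  total <- sum(segs$duration_s)
  n <- round(total * fps) + 1L
  t <- (seq_len(n) - 1L) * dt

  bounds <- c(0, cumsum(segs$duration_s))
  seg_of <- pmin(findInterval(t, bounds, rightmost.closed = TRUE),
                 nrow(segs))
  state <- segs$state[seg_of]
  f <- segs$freq_cyc_s[seg_of]
  amp <- segs$amp_rad[seg_of]
  speed <- segs$speed_mm_s[seg_of]
  dphi_dt <- ifelse(state == "forward", f,
                    ifelse(state == "reverse", -f, 0))
  # rate-limited deceleration/acceleration at segment boundaries: the
  # undulation slows to zero into each transition and ramps back out, so
  # |d omega/dt| never exceeds trans_rate_cap (real worms change phase
  # velocity smoothly; the spike filter treats faster changes as
  # physiologically impossible)
  cap <- schedule$trans_rate_cap %||% 1.6    # cycles/s^2
  fac <- rep(1, n)
  for (b in which(diff(seg_of) != 0) + 1L) {
    va <- dphi_dt[b - 1L]; vb <- dphi_dt[b]
    na_ <- ceiling(abs(va) / cap * fps)
    nb_ <- ceiling(abs(vb) / cap * fps)
    if (na_ > 0) for (k in seq_len(min(na_, b - 1L)))
      fac[b - k] <- min(fac[b - k], k / na_)
    if (nb_ > 0) for (k in seq_len(min(nb_, n - b + 1L)))
      fac[b + k - 1L] <- min(fac[b + k - 1L], k / nb_)
  }
  dphi_dt <- dphi_dt * fac
  phase <- c(0, cumsum(dphi_dt[-1] * dt))

  # turn bend fraction: raised-cosine ramp in and out within each turn segment
  bend <- numeric(n)
  ramp <- schedule$turn_ramp_s
  for (k in which(segs$state == "turn")) {
    idx <- which(seg_of == k)
    if (!length(idx)) next
    u <- t[idx] - bounds[k]
    D <- segs$duration_s[k]
    r <- rep(1, length(u))
    r[u < ramp] <- 0.5 * (1 - cos(pi * u[u < ramp] / ramp))
    tail_u <- D - u
    r[tail_u < ramp] <- pmin(r[tail_u < ramp],
                             0.5 * (1 - cos(pi * tail_u[tail_u < ramp] / ramp)))
    bend[idx] <- r
  }

  set.seed(schedule$seed)
  heading <- numeric(n)
  heading[1] <- stats::runif(1, 0, 2 * pi)
  turn_turns <- which(segs$state == "turn")
  turn_delta <- stats::runif(max(1, length(turn_turns)), pi * 0.5, pi) *
    sample(c(-1, 1), max(1, length(turn_turns)), replace = TRUE)
  wander <- if (schedule$heading_wander_rad > 0)
    stats::rnorm(n, 0, schedule$heading_wander_rad) else numeric(n)
  dhead <- wander
  for (j in seq_along(turn_turns)) {
    idx <- which(seg_of == turn_turns[j])
    if (!length(idx)) next
    w <- bend[idx]
    if (sum(w) > 0) dhead[idx] <- dhead[idx] + turn_delta[j] * w / sum(w)
  }
  heading <- heading[1] + c(0, cumsum(dhead[-1]))

  # centroid path
  vx <- speed * cos(heading) * ifelse(state == "reverse", -1, 1)
  vy <- speed * sin(heading) * ifelse(state == "reverse", -1, 1)
  cx <- c(0, cumsum(vx[-1] * dt))
  cy <- c(0, cumsum(vy[-1] * dt))

  # skeletons
  N <- n_points
  s_mid <- (seq_len(N - 1) - 0.5) / (N - 1)  # arc-length fractions, midpoints
  ds <- L / (N - 1)
  skel <- array(NA_real_, dim = c(N, 2, n))
  amp_eff <- amp * (1 - bend)
  theta_turn <- schedule$turn_depth_rad * bend
  for (i in seq_len(n)) {
    psi <- (heading[i] + pi) +
      amp_eff[i] * sin(2 * pi * (s_mid * L / lambda - phase[i])) +
      theta_turn[i] * (s_mid - 0.5)
    x <- c(0, cumsum(ds * cos(psi)))
    y <- c(0, cumsum(ds * sin(psi)))
    skel[, 1, i] <- x - mean(x) + cx[i]
    skel[, 2, i] <- y - mean(y) + cy[i]
  }
  headtail <- sqrt((skel[1, 1, ] - skel[N, 1, ])^2 +
                   (skel[1, 2, ] - skel[N, 2, ])^2)

  # tracking stage follows the centroid with a first-order servo
  sx <- numeric(n); sy <- numeric(n)
  sx[1] <- cx[1]; sy[1] <- cy[1]
  for (i in 2:n) {
    sx[i] <- sx[i - 1] + stage_gain * (cx[i] - sx[i - 1])
    sy[i] <- sy[i - 1] + stage_gain * (cy[i] - sy[i - 1])
  }

  frames <- data.frame(
    frame = seq_len(n), time_s = t, state = state,
    centroid_x_mm = cx, centroid_y_mm = cy,
    phase_cycles = phase, phase_vel_cyc_s = dphi_dt,
    stage_x_mm = sx, stage_y_mm = sy,
    heading_rad = heading, headtail_mm = headtail,
    turn_bend = bend, stringsAsFactors = FALSE)
  out <- list(frames = frames, skeletons = skel, schedule = schedule,
              stimuli = data.frame())
  class(out) <- "worm_ground_truth"
  out
}

#' @export
print.worm_ground_truth <- function(x, ...) {
  cat(sprintf("Ground-truth worm track: %d frames at %g Hz (%.1f s), %d stimuli\n",
              nrow(x$frames), x$schedule$frame_rate,
              max(x$frames$time_s), nrow(x$stimuli)))
  print(table(x$frames$state))
  invisible(x)
}

#' Attach scripted stimulus events to a ground-truth track
#'
#' Each event is targeted at the midpoint of the anterior fifth of the body
#' (the head-targeting convention of the tracking system) at the frame
#' nearest the requested time.
#'
#' @param truth `worm_ground_truth`.
#' @param times_s stimulus onset times (s).
#' @param current_mA laser diode current (the study used 37.5-375 mA).
#' @param duration_ms pulse duration (100 ms standard).
#' @param lens_mm focusing lens focal length (75 or 100 mm).
#' @param fraction body fraction defining the targeted region (default 0.2,
#'   the anterior fifth; the target point is at arc-length `fraction/2`).
#' @return `truth` with a populated `$stimuli` data.frame.
#' @export
script_stimuli <- function(truth, times_s, current_mA = 75,
                           duration_ms = 100, lens_mm = 75, fraction = 0.2) {
  stopifnot(inherits(truth, "worm_ground_truth"))
  t <- truth$frames$time_s
  ev <- lapply(times_s, function(ts) {
    if (ts < min(t) || ts > max(t))
      stop(sprintf("stimulus time %.2f s outside recording span", ts))
    fr <- which.min(abs(t - ts))
    sk <- truth$skeletons[, , fr]
    tgt <- resample_polyline(sk, 201)[round(fraction / 2 * 200) + 1L, ]
    data.frame(time_s = t[fr], frame = fr,
               target_x_mm = tgt[1], target_y_mm = tgt[2],
               current_mA = current_mA, duration_ms = duration_ms,
               lens_mm = lens_mm)
  })
  truth$stimuli <- do.call(rbind, ev)
  truth
}

#' Rendering optics for synthetic recordings
#'
#' @param img_px image height and width in pixels.
#' @param bg_level,worm_level mean background and worm intensity in [0, 1]
#'   (dark worm on a light field by default; swap for inverse polarity).
#' @param noise_sd additive Gaussian noise sd (default 2% of the
#'   background-worm contrast).
#' @param half_width_mm worm half width at mid-body (adults are ~80 um wide).
#' @param taper exponent of the sine width profile toward the tips.
#' @param texture_amp sd of the static background texture.
#' @param texture_scale_mm wavelength range of the background texture.
#' @param n_texture number of random plane-wave texture components.
#' @param seed seed for texture and noise.
#' @return list of class `render_optics`.
#' @export
render_optics <- function(img_px = c(160, 160), bg_level = 0.75,
                          worm_level = 0.35, noise_sd = 0.008,
                          half_width_mm = 0.04, taper = 0.4,
                          texture_amp = 0.04,
                          texture_scale_mm = c(0.05, 0.4),
                          n_texture = 150, seed = 99L) {
  out <- list(img_px = as.integer(img_px), bg_level = bg_level,
              worm_level = worm_level, noise_sd = noise_sd,
              half_width_mm = half_width_mm, taper = taper,
              texture_amp = texture_amp, texture_scale_mm = texture_scale_mm,
              n_texture = as.integer(n_texture), seed = as.integer(seed))
  class(out) <- "render_optics"
  out
}

#' Static background texture model
#'
#' A sum of random plane waves — a smooth, broadband function of world
#' coordinates, so rendered frames shift rigidly (and subpixel-exactly)
#' with the stage. Exposed so registration fixtures can be built without a
#' worm in the scene.
#'
#' @param optics [render_optics()] (texture parameters and seed).
#' @return list of plane-wave parameters for [texture_field()].
#' @export
make_texture <- function(optics) {
  set.seed(optics$seed)
  nt <- optics$n_texture
  ang <- stats::runif(nt, 0, 2 * pi)
  wl <- stats::runif(nt, optics$texture_scale_mm[1], optics$texture_scale_mm[2])
  k <- 2 * pi / wl
  a <- abs(stats::rnorm(nt))
  a <- a / sqrt(sum(a^2) / 2) * optics$texture_amp  # sd of sum ~ texture_amp
  list(kx = k * cos(ang), ky = k * sin(ang), ph = stats::runif(nt, 0, 2 * pi),
       amp = a)
}

#' @rdname make_texture
#' @param tex texture from `make_texture`.
#' @param xw,yw world coordinates (mm) of the pixel columns and rows.
#' @return `texture_field` returns the intensity matrix (rows = y).
#' @export
texture_field <- function(tex, xw, yw) {
  nt <- length(tex$kx)
  Mx <- cbind(cos(outer(xw, tex$kx)), sin(outer(xw, tex$kx)))  # W x 2nt
  My <- rbind(cos(outer(tex$ky, yw) + tex$ph) * tex$amp,
              -sin(outer(tex$ky, yw) + tex$ph) * tex$amp)      # 2nt x H
  t(Mx %*% My)  # H x W  (rows = y, cols = x)
}

#' Rasterize a worm midline into a binary body mask
#'
#' Paints the tapered-width body of a skeleton (world mm) onto the pixel
#' grid of one frame. Used by the renderer and as the ground-truth mask
#' oracle for segmentation tests.
#'
#' @param skel_mm N x 2 midline in world mm, head first.
#' @param stage_mm length-2 stage position (world mm of the frame centre).
#' @param optics [render_optics()].
#' @param pixel_size_mm camera scale.
#' @return logical H x W matrix (rows = y, cols = x).
#' @export
rasterize_worm <- function(skel_mm, stage_mm, optics, pixel_size_mm) {
  H <- optics$img_px[1]; W <- optics$img_px[2]
  L <- polyline_length(skel_mm)
  nd <- max(100L, 4L * ceiling(L / pixel_size_mm))
  dense <- resample_polyline(skel_mm, nd)
  sfrac <- seq(0, 1, length.out = nd)
  wmm <- optics$half_width_mm * sin(pi * sfrac)^optics$taper
  cxpix <- (dense[, 1] - stage_mm[1]) / pixel_size_mm + (W + 1) / 2
  cypix <- (dense[, 2] - stage_mm[2]) / pixel_size_mm + (H + 1) / 2
  rpix <- wmm / pixel_size_mm
  m <- matrix(FALSE, H, W)
  for (k in seq_len(nd)) {
    r <- rpix[k]
    if (r <= 0) next
    x0 <- max(1L, floor(cxpix[k] - r)); x1 <- min(W, ceiling(cxpix[k] + r))
    y0 <- max(1L, floor(cypix[k] - r)); y1 <- min(H, ceiling(cypix[k] + r))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((ys - cypix[k])^2, (xs - cxpix[k])^2, `+`)
    m[ys, xs] <- m[ys, xs] | (d2 <= r^2)
  }
  m
}

#' Render a ground-truth track to a synthetic image stack
#'
#' Rasterizes each frame's skeleton with a tapered width profile, composites
#' it over a static textured background (fixed in world coordinates, so the
#' field shifts with the stage and registration is testable), and adds
#' Gaussian noise. Frames where the worm leaves the field of view are
#' reported in `$flagged_frames`, never silently dropped.
#'
#' @param truth `worm_ground_truth`.
#' @param optics [render_optics()].
#' @return object of class `synthetic_recording`: `$stack` (list of H x W
#'   matrices in [0,1]), `$timestamps`, `$stage_reported` (data.frame, mm),
#'   `$stimuli`, `$truth`, `$optics`, `$pixel_size_mm`, `$frame_rate`,
#'   `$flagged_frames`.
#' @export
render_frames <- function(truth, optics = render_optics()) {
  stopifnot(inherits(truth, "worm_ground_truth"))
  n <- nrow(truth$frames)
  if (n == 0L) stop("ground truth is empty")
  px <- truth$schedule$pixel_size_mm
  L <- truth$schedule$worm_length_mm
  if (2 * optics$half_width_mm >= L)
    stop("worm width must be smaller than worm length")
  H <- optics$img_px[1]; W <- optics$img_px[2]
  tex <- make_texture(optics)
  set.seed(optics$seed + 1L)
  stack <- vector("list", n)
  flagged <- integer(0)
  margin <- 3
  for (i in seq_len(n)) {
    st <- c(truth$frames$stage_x_mm[i], truth$frames$stage_y_mm[i])
    xw <- st[1] + ((1:W) - (W + 1) / 2) * px
    yw <- st[2] + ((1:H) - (H + 1) / 2) * px
    bgf <- optics$bg_level + texture_field(tex, xw, yw)
    body <- rasterize_worm(truth$skeletons[, , i], st, optics, px)
    img <- bgf
    img[body] <- optics$worm_level
    if (optics$noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, optics$noise_sd), H, W)
    stack[[i]] <- pmin(pmax(img, 0), 1)
    sx <- (truth$skeletons[, 1, i] - st[1]) / px + (W + 1) / 2
    sy <- (truth$skeletons[, 2, i] - st[2]) / px + (H + 1) / 2
    if (any(sx < 1 + margin | sx > W - margin | sy < 1 + margin |
            sy > H - margin))
      flagged <- c(flagged, i)
  }
  out <- list(stack = stack, timestamps = truth$frames$time_s,
              stage_reported = truth$frames[, c("frame", "stage_x_mm",
                                                "stage_y_mm")],
              stimuli = truth$stimuli, truth = truth, optics = optics,
              pixel_size_mm = px, frame_rate = truth$schedule$frame_rate,
              flagged_frames = flagged)
  class(out) <- "synthetic_recording"
  out
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "Synthetic recording: %d frames %dx%d px, %g Hz, %d flagged out-of-view\n",
    length(x$stack), x$optics$img_px[1], x$optics$img_px[2], x$frame_rate,
    length(x$flagged_frames)))
  invisible(x)
}

#' Convert a world-mm point to pixel coordinates of one frame
#' @param p_mm length-2 world point (mm).
#' @param stage_mm length-2 stage position (mm).
#' @param optics [render_optics()] (for the image size).
#' @param pixel_size_mm camera scale.
#' @return length-2 pixel coordinates (x, y), 1-based pixel centres.
#' @export
world_to_frame_px <- function(p_mm, stage_mm, optics, pixel_size_mm) {
  H <- optics$img_px[1]; W <- optics$img_px[2]
  c((p_mm[1] - stage_mm[1]) / pixel_size_mm + (W + 1) / 2,
    (p_mm[2] - stage_mm[2]) / pixel_size_mm + (H + 1) / 2)
}

#' Write / read a synthetic recording to a directory
#'
#' The stack goes to a multi-page 16-bit TIFF, the ground truth and stage
#' positions to CSV, and the stimulus log to JSON.
#'
#' @param rec `synthetic_recording`.
#' @param dir output directory (created if needed).
#' @return `read_recording` returns the recording (without ground-truth
#'   skeletons unless present on disk).
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(rec$stack, file.path(dir, "stack.tif"),
                  bits.per.sample = 16L)
  gt <- rec$truth$frames
  utils::write.csv(gt[, c("frame", "time_s", "state", "centroid_x_mm",
                          "centroid_y_mm", "phase_cycles")],
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(rec$stage_reported, file.path(dir, "stage.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(frame_rate = rec$frame_rate,
                            pixel_size_mm = rec$pixel_size_mm,
                            stimuli = rec$stimuli),
                       file.path(dir, "stimuli.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  stack <- tiff::readTIFF(file.path(dir, "stack.tif"), all = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "stimuli.json"),
                              simplifyVector = TRUE)
  stage <- utils::read.csv(file.path(dir, "stage.csv"))
  gt <- utils::read.csv(file.path(dir, "ground_truth.csv"))
  structure(list(stack = stack, timestamps = gt$time_s,
                 stage_reported = stage,
                 stimuli = as.data.frame(meta$stimuli),
                 truth = NULL, ground_truth_frames = gt,
                 optics = render_optics(img_px = dim(stack[[1]])),
                 pixel_size_mm = meta$pixel_size_mm,
                 frame_rate = meta$frame_rate,
                 flagged_frames = integer(0)),
            class = "synthetic_recording")
}
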