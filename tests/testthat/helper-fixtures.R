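# Shared fixtures, built in code and memoized across test files.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# short forward-crawling recording with rendered frames
fwd_recording <- function() memo("fwd_rec", {
  sch <- locomotion_schedule(data.frame(state = "forward", duration_s = 8),
                             seed = 3L)
  tr <- generate_track(sch)
  render_frames(tr, render_optics())
})

# escape-motif recording (reverse -> turn -> forward), rendered
escape_recording <- function() memo("esc_rec", {
  sch <- escape_schedule(pre_s = 3, rev_s = 1.5, turn_s = 1.5, post_s = 3,
                         seed = 5L)
  tr <- script_stimuli(generate_track(sch), 3)
  render_frames(tr, render_optics())
})

# deep self-occluding loop recording (interior hole during the turn)
loop_recording <- function() memo("loop_rec", {
  sch <- escape_schedule(pre_s = 1.5, rev_s = 0.5, turn_s = 2, post_s = 1.5,
                         seed = 5L, turn_depth_rad = 10)
  render_frames(generate_track(sch), render_optics())
})

true_mask <- function(rec, i) {
  tr <- rec$truth
  rasterize_worm(tr$skeletons[, , i],
                 c(tr$frames$stage_x_mm[i], tr$frames$stage_y_mm[i]),
                 rec$optics, rec$pixel_size_mm)
}

true_skeleton_px <- function(rec, i) {
  tr <- rec$truth
  st <- c(tr$frames$stage_x_mm[i], tr$frames$stage_y_mm[i])
  H <- rec$optics$img_px[1]; W <- rec$optics$img_px[2]
  cbind((tr$skeletons[, 1, i] - st[1]) / rec$pixel_size_mm + (W + 1) / 2,
        (tr$skeletons[, 2, i] - st[2]) / rec$pixel_size_mm + (H + 1) / 2)
}

expected_worm_area <- function(rec)
  0.85 * rec$truth$schedule$worm_length_mm * 0.08 / rec$pixel_size_mm^2

iou <- function(a, b) sum(a & b) / sum(a | b)

rmse_curves <- function(a, b) {
  a <- resample_polyline(a, nrow(b))
  e1 <- sqrt(mean(rowSums((a - b)^2)))
  e2 <- sqrt(mean(rowSums((a[rev(seq_len(nrow(a))), ] - b)^2)))
  min(e1, e2)
}

# pair of texture-background frames with a known subpixel stage shift (px)
shifted_frames <- function(shift_px, img = 96L, seed = 99L,
                           noise_sd = 0) {
  opt <- render_optics(img_px = c(img, img), seed = seed)
  tex <- make_texture(opt)
  px <- 0.0125
  mk <- function(sx, sy) {
    xw <- sx + ((1:img) - (img + 1) / 2) * px
    yw <- sy + ((1:img) - (img + 1) / 2) * px
    0.75 + texture_field(tex, xw, yw)
  }
  a <- mk(0, 0)
  b <- mk(shift_px[1] * px, shift_px[2] * px)
  if (noise_sd > 0) {
    set.seed(seed + 1L)
    a <- a + matrix(rnorm(img^2, 0, noise_sd), img, img)
    b <- b + matrix(rnorm(img^2, 0, noise_sd), img, img)
  }
  # stage shift +s moves image content by -s
  list(a = a, b = b, true_image_shift = -shift_px)
}

# independent brute-force shift oracle: scan candidate shifts on a fine
# grid, realising each candidate by an exact Fourier shift of frame b and
# scoring the normalized correlation over the central (wrap-free) region
oracle_shift <- function(a, b, center, half = 1, step = 1 / 20,
                         margin = 12L) {
  H <- nrow(a); W <- ncol(a)
  core <- function(m) m[(margin + 1):(H - margin), (margin + 1):(W - margin)]
  fb <- stats::fft(b)
  fy <- 0:(H - 1); fy[fy > H / 2] <- fy[fy > H / 2] - H
  fx <- 0:(W - 1); fx[fx > W / 2] <- fx[fx > W / 2] - W
  a0 <- core(a); a0 <- a0 - mean(a0)
  best <- c(NA, NA); best_cc <- -Inf
  for (uy in seq(center[2] - half, center[2] + half, by = step)) {
    ry <- exp(2i * pi * fy * uy / H)
    for (ux in seq(center[1] - half, center[1] + half, by = step)) {
      rx <- exp(2i * pi * fx * ux / W)
      bs <- Re(stats::fft(fb * outer(ry, rx), inverse = TRUE)) / (H * W)
      b0 <- core(bs); b0 <- b0 - mean(b0)
      cc <- sum(a0 * b0) / sqrt(sum(a0^2) * sum(b0^2))
      if (cc > best_cc) { best_cc <- cc; best <- c(ux, uy) }
    }
  }
  best
}
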