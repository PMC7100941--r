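# Synthetic dual-excitation ratiometric thermometry stacks.
#
# Emulates BCECF/TRIS imaging of the infrared pulse: the 490 nm-excitation
# channel is acquired every frame, the temperature-insensitive 440 nm channel
# only at the start and end of the session (and drifts linearly in between);
# the 490/440 ratio encodes a spatial Gaussian temperature rise that decays
# exponentially after each pulse.

#' Generate a synthetic thermometry session with known ground truth
#'
#' @param amplitude_C peak temperature rise at the beam centre (deg C); the
#'   study's pulses stayed below ~1.2 deg C at behavioral powers.
#' @param sigma_um spatial Gaussian sd of the heated spot (the beam FWHM was
#'   ~200 um, i.e. sigma ~ 85 um).
#' @param decay_s exponential decay constant of the temperature transient
#'   (~2.5 s back to baseline).
#' @param slope_per_C true ratio change per deg C.
#' @param n_pulses number of pulses (>= 1), applied every `pulse_period_s`.
#' @param pulse_period_s inter-pulse period (6 s in the study).
#' @param img_px field size (rows, cols); must contain the analysis ROI.
#' @param pixel_size_um camera scale (default 37.4/60 so a 60 px diameter is
#'   exactly 37.4 um).
#' @param frame_rate 490-channel frame rate (~20 fps).
#' @param lead_s quiet time before the first pulse.
#' @param R0 baseline 490/440 ratio.
#' @param I440_counts mean 440-channel intensity (counts).
#' @param drift_frac fractional linear drift of the 440 channel over the
#'   session (interpolated away by the analysis).
#' @param noise_sd Gaussian noise sd on the 490 channel (counts); 0 disables.
#' @param cal_jitter fractional offset applied antisymmetrically to the
#'   pre/post calibration slopes (their average stays at `slope_per_C`).
#' @param cal_temps_C calibration set-point temperatures.
#' @param seed RNG seed.
#' @return object of class `thermo_stack` with the 490-channel stack, the two
#'   440 endpoint frames, timestamps, pulse onsets, pre/post calibration
#'   tables, and ground truth (`$true_shape` Gaussian field, `$true_fac`
#'   per-frame amplitude factor in deg C, beam centre, true slope).
#' @export
generate_thermo_stack <- function(amplitude_C, sigma_um = 85, decay_s = 2.5,
                                  slope_per_C = 0.01, n_pulses = 25,
                                  pulse_period_s = 6, img_px = c(101, 101),
                                  pixel_size_um = 37.4 / 60,
                                  frame_rate = 20, lead_s = 1,
                                  R0 = 1.5, I440_counts = 500,
                                  drift_frac = 0.05, noise_sd = 1,
                                  cal_jitter = 0.01,
                                  cal_temps_C = c(23, 24, 25, 26),
                                  seed = 1L) {
  if (!is.finite(amplitude_C) || amplitude_C < 0)
    stop("'amplitude_C' must be >= 0")
  if (sigma_um <= 0) stop("'sigma_um' must be positive")
  if (decay_s <= 0) stop("'decay_s' must be positive")
  if (slope_per_C == 0) stop("'slope_per_C' must be nonzero")
  if (n_pulses < 1) stop("need at least one pulse")
  set.seed(seed)
  H <- img_px[1]; W <- img_px[2]
  dt <- 1 / frame_rate
  total_s <- lead_s + n_pulses * pulse_period_s
  t <- seq(0, total_s, by = dt)
  n <- length(t)
  onsets <- lead_s + (seq_len(n_pulses) - 1) * pulse_period_s

  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  xs <- ((1:W) - cx) * pixel_size_um
  ys <- ((1:H) - cy) * pixel_size_um
  shape <- exp(-outer(ys^2, xs^2, `+`) / (2 * sigma_um^2))  # peak 1 at centre

  fac <- numeric(n)  # deg C at beam centre, summed over pulses
  for (on in onsets) {
    active <- t >= on
    fac[active] <- fac[active] + amplitude_C * exp(-(t[active] - on) / decay_s)
  }

  drift <- 1 + drift_frac * t / total_s
  I440_base <- matrix(I440_counts, H, W)
  I440_start <- I440_base * drift[1]
  I440_end <- I440_base * drift[n]

  stack <- vector("list", n)
  for (i in seq_len(n)) {
    ratio <- R0 + slope_per_C * fac[i] * shape
    img <- I440_base * drift[i] * ratio
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
    stack[[i]] <- img
  }

  cal_tab <- function(slope) {
    data.frame(temp_C = cal_temps_C,
               ratio = R0 + slope * (cal_temps_C - cal_temps_C[1]))
  }
  out <- list(I490 = stack, I440_start = I440_start, I440_end = I440_end,
              timestamps = t, onsets = onsets,
              cal_pre = cal_tab(slope_per_C * (1 + cal_jitter)),
              cal_post = cal_tab(slope_per_C * (1 - cal_jitter)),
              true_shape = shape, true_fac = fac,
              center_px = c(cx, cy), slope_per_C = slope_per_C,
              amplitude_C = amplitude_C, sigma_um = sigma_um,
              decay_s = decay_s, pixel_size_um = pixel_size_um,
              frame_rate = frame_rate, R0 = R0)
  class(out) <- "thermo_stack"
  out
}

#' @export
print.thermo_stack <- function(x, ...) {
  cat(sprintf(
    "Thermometry stack: %d frames %dx%d px, %d pulses of %.2f degC, sigma %.0f um\n",
    length(x$I490), nrow(x$I490[[1]]), ncol(x$I490[[1]]),
    length(x$onsets), x$amplitude_C, x$sigma_um))
  invisible(x)
}

#' Analytic mean of a Gaussian temperature field over a centred circular ROI
#'
#' For a field `A * exp(-r^2 / (2 sigma^2))`, the mean over a disk of radius
#' R centred on the peak is `A * (2 sigma^2 / R^2) * (1 - exp(-R^2/(2 sigma^2)))`.
#' Used as the closed-form oracle for ROI-averaged peak recovery.
#'
#' @param amplitude_C peak value.
#' @param sigma_um Gaussian sd.
#' @param roi_diameter_um ROI diameter.
#' @return analytic disk-averaged value.
#' @export
gaussian_disk_mean <- function(amplitude_C, sigma_um, roi_diameter_um) {
  R <- roi_diameter_um / 2
  amplitude_C * (2 * sigma_um^2 / R^2) * (1 - exp(-R^2 / (2 * sigma_um^2)))
}
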