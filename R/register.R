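# Stage-motion registration, coordinate calibrations, and laser targeting.

#' Affine calibration between two coordinate systems
#'
#' Least-squares affine fit `to = M %*% from + b` (pixel to mm, or volt to
#' pixel). Requires at least three non-collinear points.
#'
#' @param from n x 2 matrix of source coordinates.
#' @param to n x 2 matrix of target coordinates.
#' @return object of class `calibration_transform`: `M` (2 x 2), `b`
#'   (length 2), `residual` (RMS over the fit points), `condition`.
#' @export
fit_affine_calibration <- function(from, to) {
  from <- as.matrix(from); to <- as.matrix(to)
  if (nrow(from) < 3L)
    stop("need at least 3 calibration points, got ", nrow(from))
  ctr <- sweep(from, 2, colMeans(from))
  sv <- svd(ctr)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("calibration points are collinear; affine fit is underdetermined")
  X <- cbind(1, from)
  beta <- qr.solve(X, to)              # 3 x 2: offset then matrix rows
  M <- t(beta[2:3, , drop = FALSE])
  b <- as.numeric(beta[1, ])
  pred <- from %*% t(M) + matrix(b, nrow(from), 2, byrow = TRUE)
  cond <- {
    s <- svd(M)$d
    if (s[2] <= 0) Inf else s[1] / s[2]
  }
  if (cond >= 1e6) stop("calibration matrix is numerically singular")
  structure(list(M = M, b = b,
                 residual = sqrt(mean(rowSums((to - pred)^2))),
                 condition = cond),
            class = "calibration_transform")
}

#' @export
print.calibration_transform <- function(x, ...) {
  cat("Affine calibration: M =\n"); print(x$M)
  cat(sprintf("offset (%.4g, %.4g), residual %.4g, condition %.3g\n",
              x$b[1], x$b[2], x$residual, x$condition))
  invisible(x)
}

#' Apply / invert a calibration transform
#' @param cal `calibration_transform`.
#' @param pts n x 2 matrix or length-2 vector.
#' @return transformed coordinates (same shape as input).
#' @export
apply_calibration <- function(cal, pts) {
  v <- is.null(dim(pts))
  p <- if (v) matrix(pts, 1) else as.matrix(pts)
  out <- p %*% t(cal$M) + matrix(cal$b, nrow(p), 2, byrow = TRUE)
  if (v) as.numeric(out) else out
}

#' @rdname apply_calibration
#' @export
invert_calibration <- function(cal) {
  Mi <- solve(cal$M)
  structure(list(M = Mi, b = as.numeric(-Mi %*% cal$b),
                 residual = cal$residual, condition = cal$condition),
            class = "calibration_transform")
}

#' Diagonal calibration from a known pixel size
#' @param scale_x,scale_y mm per pixel along each axis (sign encodes axis
#'   inversion).
#' @return `calibration_transform`.
#' @export
simple_calibration <- function(scale_x, scale_y = scale_x) {
  structure(list(M = diag(c(scale_x, scale_y)), b = c(0, 0),
                 residual = 0, condition = max(abs(c(scale_x, scale_y))) /
                   min(abs(c(scale_x, scale_y)))),
            class = "calibration_transform")
}

#' Calibrate the stage from a tracked stationary object
#'
#' The pixel position of a stationary object (a speck of dust) is recorded
#' while the stage executes commanded moves; the affine pixel-to-mm map is
#' fitted by least squares.
#'
#' @param object_px n x 2 pixel positions of the tracked object.
#' @param stage_mm n x 2 commanded stage positions (mm).
#' @return `calibration_transform` mapping pixel to mm.
#' @export
calibrate_stage <- function(object_px, stage_mm)
  fit_affine_calibration(object_px, stage_mm)

#' Calibrate the galvanometer mirrors from burn-spot positions
#'
#' The beam is steered to a set of voltage pairs and the user clicks the
#' burnt spot in the image; both directions of the affine volt/pixel map are
#' returned.
#'
#' @param volts n x 2 commanded galvo voltages.
#' @param beam_px n x 2 observed beam pixel positions.
#' @return list: `volt_to_px`, `px_to_volt` (both `calibration_transform`).
#' @export
calibrate_galvo <- function(volts, beam_px) {
  v2p <- fit_affine_calibration(volts, beam_px)
  list(volt_to_px = v2p, px_to_volt = invert_calibration(v2p))
}

#' Subpixel image shift by masked normalized cross-correlation
#'
#' Estimates the translation taking `frame_a` into `frame_b` (positive dx:
#' content moved right / toward larger x). The normalized cross-correlation
#' of the masked, zero-padded frames is computed in the Fourier domain with
#' per-offset mean and variance normalization (which removes the bias the
#' finite aperture induces in plain correlation), the integer peak is
#' located, and the surface is then refined around it by evaluating its
#' constituent band-limited correlation surfaces on a fine grid with
#' matrix-multiply discrete Fourier transforms (local upsampling, default
#' 1/100 px in two stages).
#'
#' @param frame_a,frame_b grayscale matrices of equal size.
#' @param mask optional logical matrix, TRUE where pixels may be used (e.g.
#'   a border region that excludes the worm body).
#' @param usfac upsampling factor for the subpixel refinement.
#' @param search_px maximum shift magnitude considered (px).
#' @param min_overlap_frac minimum mask-overlap fraction for a candidate
#'   offset.
#' @return list: `shift` (c(dx, dy), px), `confidence` (peak normalized
#'   correlation in [-1, 1]), `low_confidence` flag (also set for
#'   textureless regions, with shift (0, 0)).
#' @export
estimate_shift <- function(frame_a, frame_b, mask = NULL, usfac = 100L,
                           search_px = 15, min_overlap_frac = 0.3) {
  H <- nrow(frame_a); W <- ncol(frame_a)
  stopifnot(all(dim(frame_b) == c(H, W)))
  # per-offset normalization makes the correlation insensitive to the
  # weighting window, so a Hann taper can be used to suppress aperture
  # ripple when no mask restricts the usable region
  w <- if (is.null(mask))
    outer(0.5 - 0.5 * cos(2 * pi * (1:H - 1) / (H - 1)),
          0.5 - 0.5 * cos(2 * pi * (1:W - 1) / (W - 1)))^0.5
  else mask * 1
  if (stats::sd(frame_a[w > 0]) < 1e-9 || stats::sd(frame_b[w > 0]) < 1e-9)
    return(list(shift = c(0, 0), confidence = 0, low_confidence = TRUE))
  pad <- function(m) { o <- matrix(0, 2 * H, 2 * W); o[1:H, 1:W] <- m; o }
  fa <- stats::fft(pad(frame_a * w)); fb <- stats::fft(pad(frame_b * w))
  fm <- stats::fft(pad(w))
  fa2 <- stats::fft(pad(frame_a^2 * w)); fb2 <- stats::fft(pad(frame_b^2 * w))
  # spectra of the correlation surfaces (correlate x with y: Conj(Fx)*Fy)
  S <- list(fg = Conj(fa) * fb, f1 = Conj(fa) * fm, g1 = Conj(fm) * fb,
            mm = Conj(fm) * fm, ff = Conj(fa2) * fm, gg = Conj(fm) * fb2)
  n2 <- 4 * H * W
  ncc_of <- function(l, mm_max) {
    ov <- pmax(l$mm, 1e-9)
    num <- l$fg - l$f1 * l$g1 / ov
    den <- sqrt(pmax(l$ff - l$f1^2 / ov, 0) * pmax(l$gg - l$g1^2 / ov, 0))
    out <- num / pmax(den, 1e-9)
    out[l$mm < min_overlap_frac * mm_max] <- -Inf
    out
  }
  surf <- lapply(S, function(s) Re(stats::fft(s, inverse = TRUE)) / n2)
  mm_max <- max(surf$mm)
  cc <- ncc_of(surf, mm_max)
  fy <- 0:(2 * H - 1); fy[fy > H] <- fy[fy > H] - 2 * H
  fx <- 0:(2 * W - 1); fx[fx > W] <- fx[fx > W] - 2 * W
  ok <- outer(abs(fy) <= search_px, abs(fx) <= search_px)
  cc[!ok] <- -Inf
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ctr <- c(fx[pk[2]], fy[pk[1]])
  ky <- fy / (2 * H); kx <- fx / (2 * W)
  refine <- function(ctr, half, step) {
    uy <- ctr[2] + seq(-half, half, by = step)
    ux <- ctr[1] + seq(-half, half, by = step)
    Er <- exp(2i * pi * outer(uy, ky))
    Ec <- exp(2i * pi * outer(kx, ux))
    up <- lapply(S, function(s) Re(Er %*% s %*% Ec) / n2)
    ccu <- ncc_of(up, mm_max)
    p <- which(ccu == max(ccu), arr.ind = TRUE)[1, ]
    list(shift = c(ux[p[2]], uy[p[1]]), peak = max(ccu))
  }
  r1 <- refine(ctr, 1, 0.1)
  r2 <- if (usfac > 10L) refine(r1$shift, 0.15, 1 / usfac) else r1
  list(shift = r2$shift, confidence = r2$peak,
       low_confidence = r2$peak < 0.2)
}

#' Border-region mask for registration
#'
#' A border annulus (default 15% of the image size) minus a dilated worm
#' mask, so registration never locks onto the moving worm.
#'
#' @param dim_hw image dimensions (rows, cols).
#' @param worm_mask optional logical worm mask to exclude (dilated).
#' @param border_frac annulus width as a fraction of the smaller dimension.
#' @param dilate_px dilation radius applied to the worm mask.
#' @return logical matrix.
#' @export
edge_region_mask <- function(dim_hw, worm_mask = NULL, border_frac = 0.15,
                             dilate_px = 5L) {
  H <- dim_hw[1]; W <- dim_hw[2]
  bw <- max(8L, round(border_frac * min(H, W)))
  m <- matrix(FALSE, H, W)
  m[c(1:bw, (H - bw + 1):H), ] <- TRUE
  m[, c(1:bw, (W - bw + 1):W)] <- TRUE
  if (!is.null(worm_mask) && sum(worm_mask) > 0) {
    grown <- EBImage::dilate(worm_mask * 1,
                             EBImage::makeBrush(2L * dilate_px + 1L,
                                                shape = "disc")) > 0
    m <- m & !grown
  }
  m
}

#' Pairwise frame shifts of a recording at several lags
#'
#' @param stack list of frames.
#' @param masks optional list of worm masks (excluded from registration).
#' @param lags integer lags (default 1:3).
#' @param use_edge_mask restrict registration to the border annulus
#'   (default TRUE; set FALSE for worm-free scenes, where the whole frame
#'   is background).
#' @param ... passed to [estimate_shift()].
#' @return list of n x 2 matrices, one per lag; row i holds the shift from
#'   frame i-lag to frame i (NA where unavailable).
#' @export
register_stack <- function(stack, masks = NULL, lags = 1:3,
                           use_edge_mask = TRUE, ...) {
  n <- length(stack)
  dim_hw <- dim(stack[[1]])
  out <- lapply(lags, function(l) matrix(NA_real_, n, 2))
  names(out) <- paste0("lag", lags)
  for (li in seq_along(lags)) {
    l <- lags[li]
    for (i in (l + 1):n) {
      wm <- if (is.null(masks)) NULL else {
        a <- masks[[i - l]]; b <- masks[[i]]
        if (is.null(a)) b else if (is.null(b)) a else (a | b)
      }
      m <- if (use_edge_mask) edge_region_mask(dim_hw, wm) else NULL
      es <- estimate_shift(stack[[i - l]], stack[[i]], mask = m, ...)
      out[[li]][i, ] <- es$shift
    }
  }
  out
}

#' Integrate pairwise shifts into a stage trajectory
#'
#' The per-frame displacement is the average of the lag-1 shift with the
#' lag-2 and lag-3 shifts scaled to per-frame increments
#' (`d_i = mean(s1_i, s2_i/2, s3_i/3)`), which suppresses accumulated noise;
#' the cumulative sum is converted to mm through the calibration's linear
#' part and anchored at the reported start position. Because the image moves
#' opposite to the stage, pass `sign = -1` (default) when the shifts are
#' image-content shifts.
#'
#' @param shifts list of per-lag shift matrices from [register_stack()].
#' @param start_mm length-2 reported stage start position (mm).
#' @param cal `calibration_transform` pixel to mm.
#' @param sign +1 or -1 applied to image shifts before conversion.
#' @return data.frame: frame, x_mm, y_mm, source, interpolated flag.
#' @export
integrate_stage_motion <- function(shifts, start_mm, cal, sign = -1) {
  n <- nrow(shifts[[1]])
  lags <- as.integer(sub("lag", "", names(shifts)))
  d <- matrix(NA_real_, n, 2)
  for (i in 2:n) {
    est <- do.call(rbind, lapply(seq_along(lags), function(li) {
      l <- lags[li]
      if (i - l >= 1 && !any(is.na(shifts[[li]][i, ])))
        shifts[[li]][i, ] / l else NULL
    }))
    if (!is.null(est)) d[i, ] <- colMeans(est)
  }
  d[1, ] <- 0
  interp <- is.na(d[, 1])
  d[, 1] <- fill_na_linear(d[, 1])
  d[, 2] <- fill_na_linear(d[, 2])
  cum <- apply(d, 2, cumsum) * sign
  mm <- cum %*% t(cal$M)
  data.frame(frame = seq_len(n),
             x_mm = start_mm[1] + mm[, 1],
             y_mm = start_mm[2] + mm[, 2],
             source = "estimated",
             interpolated = interp)
}

#' Convert a pixel point of one frame to world coordinates
#'
#' `world = affine(pixel) + stage`; the affine part must map pixels (origin
#' at the frame centre) to mm. For frames whose centre pixel corresponds to
#' the stage position, subtract the centre before calling, or use
#' [frame_px_to_world()].
#'
#' @param px_pt length-2 (or n x 2) pixel coordinates.
#' @param stage_mm length-2 stage position (mm).
#' @param cal `calibration_transform` pixel to mm.
#' @return world coordinates (mm), same shape as `px_pt`.
#' @export
to_world <- function(px_pt, stage_mm, cal) {
  out <- apply_calibration(cal, px_pt)
  if (is.null(dim(out))) out + stage_mm
  else sweep(out, 2, -stage_mm, `-`)
}

#' @rdname to_world
#' @param world_mm world coordinates (mm).
#' @export
to_pixel <- function(world_mm, stage_mm, cal) {
  ical <- invert_calibration(cal)
  if (is.null(dim(world_mm))) apply_calibration(ical, world_mm - stage_mm)
  else apply_calibration(ical, sweep(as.matrix(world_mm), 2, stage_mm))
}

#' Frame-centred pixel to world conversion
#' @param px_pt pixel coordinates (1-based, as in the rendered frames).
#' @param stage_mm stage position (world mm of the frame centre).
#' @param dim_hw frame dimensions (rows, cols).
#' @param pixel_size_mm camera scale.
#' @return world mm coordinates.
#' @export
frame_px_to_world <- function(px_pt, stage_mm, dim_hw, pixel_size_mm) {
  ctr <- c((dim_hw[2] + 1) / 2, (dim_hw[1] + 1) / 2)
  if (is.null(dim(px_pt)))
    (px_pt - ctr) * pixel_size_mm + stage_mm
  else sweep(sweep(as.matrix(px_pt), 2, ctr) * pixel_size_mm, 2,
             -stage_mm, `-`)
}

#' Laser target on the worm's head
#'
#' The target is the skeleton point at arc-length `fraction/2` from the head
#' tip — the midpoint of the anterior fifth for the default fraction 0.2.
#' The predicted targeting error from the one-frame lag between measurement
#' and firing is `speed / frame_rate`.
#'
#' @param skeleton oriented, non-complex `worm_skeleton`.
#' @param fraction targeted body fraction in (0, 1].
#' @param speed_mm_s current worm speed (optional, for the lag estimate).
#' @param frame_rate acquisition rate (Hz).
#' @return list: `target_px` (c(x, y)), `arc_fraction`, `lag_error_mm`.
#' @export
target_head <- function(skeleton, fraction = 0.2, speed_mm_s = NULL,
                        frame_rate = NULL) {
  if (isTRUE(skeleton$complex) || is.null(skeleton$points))
    stop("cannot target a complex frame")
  if (!isTRUE(skeleton$oriented))
    stop("skeleton must be oriented (head known) before targeting")
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  dense <- resample_polyline(skeleton$points, 401L)
  idx <- round(fraction / 2 * 400) + 1L
  lag <- if (!is.null(speed_mm_s) && !is.null(frame_rate))
    speed_mm_s / frame_rate else NA_real_
  list(target_px = dense[idx, ], arc_fraction = fraction / 2,
       lag_error_mm = lag)
}
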