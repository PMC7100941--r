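# Posture: midline extraction, eigenworm basis, posture-space repair of
# self-occluded frames, and head-tail orientation from stimulus anchors.

circular_smooth <- function(v, w) {
  if (w < 2) return(v)
  n <- length(v)
  k <- rep(1 / w, w)
  pad <- ceiling(w / 2)
  vp <- c(v[(n - pad + 1):n], v, v[1:pad])
  out <- stats::filter(vp, k, sides = 2)
  as.numeric(out[(pad + 1):(pad + n)])
}

# interior hole presence (background components not touching the border)
has_interior_hole <- function(mask) {
  comp <- EBImage::bwlabel(!mask)
  H <- nrow(mask); W <- ncol(mask)
  border <- unique(c(comp[1, ], comp[H, ], comp[, 1], comp[, W]))
  length(setdiff(seq_len(max(comp)), c(0L, border))) > 0L
}

mask_solidity <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) < 3L) return(1)
  ch <- grDevices::chull(px)
  hull <- px[ch, , drop = FALSE]
  ha <- abs(sum(hull[, 1] * c(hull[-1, 2], hull[1, 2]) -
                hull[, 2] * c(hull[-1, 1], hull[1, 1]))) / 2
  nrow(px) / max(ha, nrow(px))
}

# walk each end of a midline along its end tangent until it leaves the mask
extend_to_mask <- function(mid, mask, step = 0.25, max_px = 6) {
  H <- nrow(mask); W <- ncol(mask)
  inside <- function(p) {
    r <- round(p[2]); c <- round(p[1])
    r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c]
  }
  m <- nrow(mid)
  for (end in c(1L, 2L)) {
    if (end == 1L) { p <- mid[1, ]; d <- mid[1, ] - mid[4, ] }
    else { p <- mid[m, ]; d <- mid[m, ] - mid[m - 3, ] }
    nd <- sqrt(sum(d^2)); if (nd < 1e-9) next
    d <- d / nd
    ext <- 0
    while (ext < max_px && inside(p + step * d)) {
      p <- p + step * d
      ext <- ext + step
    }
    if (end == 1L) mid <- rbind(p, mid) else mid <- rbind(mid, p)
  }
  mid
}

#' Extract a worm midline from a binary mask
#'
#' Boundary-based midline finding: the outline is traced and smoothed, the
#' two body tips are located as boundary-curvature extrema (constrained to
#' lie roughly half a perimeter apart, ties broken by maximal separation),
#' the outline is split into two sides, and the midline is the mean of
#' arc-length-matched side points, resampled to `n_points`. Self-occluding
#' (looped) masks are flagged complex and no skeleton is emitted.
#'
#' @param mask logical body mask (single component, quality `ok`).
#' @param n_points skeleton points N (default 49).
#' @param min_separation minimum tip separation as a fraction of perimeter.
#' @return object of class `worm_skeleton`: `points` (N x 2, columns x, y in
#'   pixel coordinates; `NULL` when complex), `length_px`, `complex`,
#'   `oriented` (FALSE until head-tail correction).
#' @export
midline_simple <- function(mask, n_points = 49, min_separation = 0.30) {
  if (is.null(mask) || sum(mask) < 10L)
    stop("mask is empty or too small for midline extraction")
  skel <- structure(list(points = NULL, length_px = NA_real_,
                         complex = TRUE, oriented = FALSE),
                    class = "worm_skeleton")
  if (has_interior_hole(mask)) return(skel)        # looped worm
  if (mask_solidity(mask) < 0.12) return(skel)     # degenerate shape
  oc <- EBImage::ocontour(mask * 1)
  if (!length(oc)) return(skel)
  bd <- oc[[which.max(vapply(oc, nrow, 0L))]] + 1  # (row, col), 1-based
  P <- nrow(bd)
  if (P < 20L) return(skel)
  x <- bd[, 2]; y <- bd[, 1]
  w <- max(7L, round(0.05 * P))
  xs <- circular_smooth(x, w); ys <- circular_smooth(y, w)
  # turning angle over a step of k points
  k <- max(3L, round(0.025 * P))
  ix <- seq_len(P)
  im <- ((ix - 1 - k) %% P) + 1; ip <- ((ix - 1 + k) %% P) + 1
  ax <- xs - xs[im]; ay <- ys - ys[im]
  bx2 <- xs[ip] - xs; by2 <- ys[ip] - ys
  ang <- abs(atan2(ax * by2 - ay * bx2, ax * bx2 + ay * by2))
  tip1 <- which.max(ang)
  circ_d <- pmin(abs(ix - tip1), P - abs(ix - tip1))
  cand <- which(circ_d >= min_separation * P)
  if (!length(cand)) return(skel)
  best <- max(ang[cand])
  ties <- cand[ang[cand] >= best - 1e-12]
  tip2 <- ties[which.max(circ_d[ties])]
  a <- min(tip1, tip2); b <- max(tip1, tip2)
  sideA <- cbind(xs, ys)[a:b, , drop = FALSE]
  sideB <- cbind(xs, ys)[c(b:P, 1:a), , drop = FALSE]
  sideB <- sideB[rev(seq_len(nrow(sideB))), , drop = FALSE]  # run a -> b
  lenA <- polyline_length(sideA); lenB <- polyline_length(sideB)
  if (max(lenA, lenB) > 2.5 * min(lenA, lenB)) return(skel)
  m <- 2L * n_points - 1L
  mid <- (resample_polyline(sideA, m) + resample_polyline(sideB, m)) / 2
  # boundary smoothing pulls the tips inward; extend each end along its
  # tangent to the mask edge to recover the true tip position
  mid <- extend_to_mask(mid, mask)
  pts <- resample_polyline(mid, n_points)
  structure(list(points = pts, length_px = polyline_length(pts),
                 complex = FALSE, oriented = FALSE),
            class = "worm_skeleton")
}

#' @export
print.worm_skeleton <- function(x, ...) {
  if (x$complex) cat("Worm skeleton: complex frame (no midline)\n")
  else cat(sprintf("Worm skeleton: %d points, length %.1f px, %soriented\n",
                   nrow(x$points), x$length_px,
                   if (x$oriented) "" else "un"))
  invisible(x)
}

#' Flag complex (self-occluded or failed) frames in a skeleton series
#'
#' Frames already flagged by the midline finder, plus skeleton-length
#' outliers beyond `tol` of the running median, plus any mask-level
#' criteria supplied (preserved loop holes, solidity drops).
#'
#' @param skeletons list of `worm_skeleton`.
#' @param tol relative length deviation marking an outlier (default 0.25).
#' @param window running-median window (frames).
#' @param extra optional logical vector of additional per-frame criteria.
#' @return integer vector of complex frame indices.
#' @export
flag_complex_frames <- function(skeletons, tol = 0.25, window = 201L,
                                extra = NULL) {
  if (!length(skeletons)) stop("empty skeleton series")
  lens <- vapply(skeletons, function(s)
    if (is.null(s)) NA_real_ else s$length_px, 0)
  comp <- vapply(skeletons, function(s)
    is.null(s) || isTRUE(s$complex), TRUE)
  med <- running_median(fill_na_linear(lens), min(window, length(lens)))
  outlier <- !is.na(lens) & abs(lens - med) > tol * med
  flags <- comp | outlier
  if (!is.null(extra)) flags <- flags | extra
  which(flags)
}

#' Build an eigenworm basis from a sample of skeletons
#'
#' Computes tangent-angle profiles, removes per-frame rigid rotation (mean
#' angle), subtracts the ensemble mean profile, and extracts the leading K
#' principal modes by singular value decomposition. On sinusoidal crawling
#' the first two modes form a quadrature pair; the sign of mode 2 is
#' calibrated so that forward crawling in the build sample winds the
#' (a1, a2) phase positively.
#'
#' @param skeletons list of non-complex, consistently oriented
#'   `worm_skeleton` objects (or an N x 2 x T array), at least `min_frames`
#'   of them, spanning the undulation cycle.
#' @param K number of modes kept (default 4).
#' @param min_frames minimum sample size.
#' @param calibrate_winding calibrate the sign of mode 2 (default TRUE;
#'   assumes the build sample is predominantly forward crawling).
#' @return object of class `eigenworm_basis`: `modes` (M x K, orthonormal),
#'   `mean_profile` (length M), `var_explained`, `M`.
#' @export
build_eigenbasis <- function(skeletons, K = 4L, min_frames = 100L,
                             calibrate_winding = TRUE) {
  A <- angle_matrix(skeletons)
  if (nrow(A) < min_frames)
    stop(sprintf("need at least %d non-complex skeletons, got %d",
                 min_frames, nrow(A)))
  A <- A - rowMeans(A)            # remove rigid rotation
  mp <- colMeans(A)
  X <- sweep(A, 2, mp)
  sv <- svd(X, nu = 0, nv = K)
  modes <- sv$v
  for (k in seq_len(K))
    if (modes[which.max(abs(modes[, k])), k] < 0) modes[, k] <- -modes[, k]
  basis <- structure(list(modes = modes, mean_profile = mp,
                          var_explained = sv$d^2 / sum(sv$d^2),
                          M = ncol(A)),
                     class = "eigenworm_basis")
  if (calibrate_winding) {
    a <- X %*% modes
    phi <- unwrap_phase(atan2(-a[, 2], a[, 1]))
    if (sum(diff(phi)) < 0) basis$modes[, 2] <- -basis$modes[, 2]
  }
  basis
}

# tangent-angle matrix (frames x M) from a skeleton list or N x 2 x T array
angle_matrix <- function(skeletons) {
  if (is.array(skeletons) && length(dim(skeletons)) == 3L) {
    n <- dim(skeletons)[3]
    t(vapply(seq_len(n), function(i) tangent_angles(skeletons[, , i]),
             numeric(dim(skeletons)[1] - 1L)))
  } else {
    keep <- Filter(function(s) !is.null(s$points) && !s$complex, skeletons)
    t(vapply(keep, function(s) tangent_angles(s$points),
             numeric(nrow(keep[[1]]$points) - 1L)))
  }
}

#' @export
print.eigenworm_basis <- function(x, ...) {
  cat(sprintf("Eigenworm basis: %d modes over %d angle samples; var explained %s\n",
              ncol(x$modes), x$M,
              paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(ncol(x$modes))]),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read an eigenworm basis as CSV
#' @param basis `eigenworm_basis`.
#' @param path file path.
#' @return `read_eigenbasis` returns an `eigenworm_basis`.
#' @export
write_eigenbasis <- function(basis, path) {
  df <- data.frame(mean_profile = basis$mean_profile, basis$modes)
  names(df)[-1] <- paste0("mode", seq_len(ncol(basis$modes)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eigenbasis
#' @export
read_eigenbasis <- function(path) {
  df <- utils::read.csv(path)
  modes <- as.matrix(df[, grep("^mode", names(df)), drop = FALSE])
  dimnames(modes) <- NULL
  structure(list(modes = modes, mean_profile = df$mean_profile,
                 var_explained = NA_real_, M = nrow(df)),
            class = "eigenworm_basis")
}

.reference_basis_cache <- new.env(parent = emptyenv())

#' Deterministic reference eigenworm basis
#'
#' Basis computed from a bundled synthetic ensemble of forward crawling at
#' three bend amplitudes plus shallow turns, generated in code (seed fixed).
#' Used as the default basis so that phase signs are reproducible across
#' recordings; an external basis can be loaded with [read_eigenbasis()].
#'
#' @param n_points skeleton points of the target skeletons.
#' @return `eigenworm_basis`.
#' @export
reference_eigenbasis <- function(n_points = 49L) {
  key <- as.character(n_points)
  if (!is.null(.reference_basis_cache[[key]]))
    return(.reference_basis_cache[[key]])
  segs <- data.frame(
    state = c("forward", "forward", "forward", "turn", "forward"),
    duration_s = c(20, 20, 20, 1.5, 5),
    speed_mm_s = 0.2, freq_cyc_s = 0.5,
    amp_rad = c(0.45, 0.55, 0.65, 0.55, 0.55))
  sch <- locomotion_schedule(segs, seed = 42L, turn_depth_rad = 2.0)
  tr <- generate_track(sch, n_points = n_points)
  basis <- build_eigenbasis(tr$skeletons, K = 4L)
  .reference_basis_cache[[key]] <- basis
  basis
}

#' Project a skeleton onto an eigenworm basis
#'
#' `a_k` is the inner product of the rotation-removed, mean-subtracted
#' tangent-angle profile with mode k.
#'
#' @param skeleton oriented, non-complex `worm_skeleton` (or an N x 2
#'   point matrix).
#' @param basis `eigenworm_basis`.
#' @return list: `a` (length K), `residual_rms` (relative RMS of the part of
#'   the profile outside the K-mode subspace), `mean_angle` (removed rigid
#'   rotation, rad).
#' @export
project_modes <- function(skeleton, basis) {
  pts <- if (is.matrix(skeleton)) skeleton else {
    if (isTRUE(skeleton$complex))
      stop("cannot project a complex frame")
    if (!isTRUE(skeleton$oriented) && !is.matrix(skeleton))
      stop("skeleton must be oriented before projection (mode signs depend on the head choice)")
    skeleton$points
  }
  th <- tangent_angles(pts)
  if (length(th) != basis$M)
    stop("skeleton resolution does not match the basis")
  alpha <- mean(th)
  v <- th - alpha - basis$mean_profile
  a <- as.numeric(crossprod(basis$modes, v))
  rec <- basis$modes %*% a
  list(a = a, residual_rms = sqrt(mean((v - rec)^2)) /
         max(sqrt(mean(v^2)), 1e-12),
       mean_angle = alpha)
}

#' Project a whole skeleton series onto a basis
#'
#' @param skeletons list of `worm_skeleton` (complex/NULL frames yield NA)
#'   or an N x 2 x T array.
#' @param basis `eigenworm_basis`.
#' @return list: `modes` (T x K matrix), `mean_angle` (length T, unwrapped
#'   over time), `residual_rms` (length T).
#' @export
project_series <- function(skeletons, basis) {
  if (is.array(skeletons)) {
    n <- dim(skeletons)[3]
    get <- function(i) skeletons[, , i]
    ok <- rep(TRUE, n)
  } else {
    n <- length(skeletons)
    get <- function(i) skeletons[[i]]$points
    ok <- vapply(skeletons, function(s)
      !is.null(s) && !is.null(s$points) && !isTRUE(s$complex), TRUE)
  }
  K <- ncol(basis$modes)
  A <- matrix(NA_real_, n, K)
  alpha <- rep(NA_real_, n)
  res <- rep(NA_real_, n)
  for (i in which(ok)) {
    th <- tangent_angles(get(i))
    al <- mean(th)
    v <- th - al - basis$mean_profile
    a <- as.numeric(crossprod(basis$modes, v))
    A[i, ] <- a
    alpha[i] <- al
    res[i] <- sqrt(mean((v - basis$modes %*% a)^2)) /
      max(sqrt(mean(v^2)), 1e-12)
  }
  list(modes = A, mean_angle = unwrap_phase(alpha), residual_rms = res)
}

# smoothing-spline fit across good frames, GCV-chosen smoothing; returns
# predictions at all frames. Falls back to linear interpolation for tiny
# samples or degenerate fits.
spline_over_gaps <- function(t, v, good) {
  out <- rep(NA_real_, length(t))
  idx <- which(good & !is.na(v))
  if (length(idx) < 4L) {
    if (length(idx) >= 2L)
      out <- stats::approx(t[idx], v[idx], xout = t, rule = 1)$y
    else if (length(idx) == 1L) out[] <- v[idx]
    return(out)
  }
  fit <- tryCatch(stats::smooth.spline(t[idx], v[idx], cv = FALSE,
                                       all.knots = TRUE),
                  error = function(e) NULL)
  if (is.null(fit))
    return(stats::approx(t[idx], v[idx], xout = t, rule = 1)$y)
  stats::predict(fit, t)$y
}

#' Interpolate posture modes across complex frames
#'
#' Each mode trajectory is fitted with a smoothing spline (smoothing chosen
#' by generalized cross-validation) over the non-complex frames and
#' evaluated everywhere, which repairs complex runs through posture space
#' and lightly smooths minor errors on all frames. Complex runs longer than
#' `max_gap_s`, and runs touching the recording boundary, are marked missing
#' rather than fabricated.
#'
#' @param modes T x K mode matrix (NA on complex frames allowed).
#' @param complex integer indices (or logical vector) of complex frames.
#' @param frame_rate Hz.
#' @param max_gap_s longest complex run that may be bridged (default 2 s).
#' @return list: `modes` (T x K completed), `missing` (logical),
#'   `reconstructed` (logical: frame values came from interpolation).
#' @export
interpolate_complex <- function(modes, complex, frame_rate, max_gap_s = 2) {
  n <- nrow(modes)
  cx <- if (is.logical(complex)) complex else seq_len(n) %in% complex
  good <- !cx & !is.na(modes[, 1])
  missing <- rep(FALSE, n)
  r <- rle(!good)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    run <- starts[j]:ends[j]
    if (starts[j] == 1L || ends[j] == n ||
        r$lengths[j] > max_gap_s * frame_rate)
      missing[run] <- TRUE
  }
  t <- seq_len(n) / frame_rate
  out <- modes
  for (k in seq_len(ncol(modes)))
    out[, k] <- spline_over_gaps(t, modes[, k], good)
  out[missing, ] <- NA_real_
  list(modes = out, missing = missing, reconstructed = !good & !missing)
}

#' Reconstruct skeletons from (interpolated) posture modes
#'
#' Rebuilds midlines for repaired frames from the K-mode angle profile, the
#' interpolated rigid rotation, a body length, and a centroid position.
#'
#' @param modes T x K matrix.
#' @param basis `eigenworm_basis`.
#' @param mean_angle length-T rigid rotation (rad, unwrapped; NA bridged).
#' @param length_px length-T body arc length (px; NA bridged by median).
#' @param centroids T x 2 centroid positions (px).
#' @param frames which frames to reconstruct (default all with finite modes).
#' @return list of `worm_skeleton` (with `$reconstructed = TRUE`), indexed
#'   as `frames`.
#' @export
reconstruct_skeletons <- function(modes, basis, mean_angle, length_px,
                                  centroids, frames = NULL) {
  n <- nrow(modes)
  if (is.null(frames)) frames <- which(is.finite(modes[, 1]))
  mean_angle <- fill_na_linear(mean_angle)
  length_px[!is.finite(length_px)] <- NA
  length_px <- fill_na_linear(length_px)
  lapply(frames, function(i) {
    th <- basis$mean_profile + as.numeric(basis$modes %*% modes[i, ]) +
      mean_angle[i]
    pts <- angles_to_midline(th, length_px[i],
                             centroid = as.numeric(centroids[i, ]))
    structure(list(points = pts, length_px = length_px[i], complex = FALSE,
                   oriented = TRUE, reconstructed = TRUE),
              class = "worm_skeleton")
  })
}

#' Correct head-tail orientation of a skeleton series
#'
#' At each anchor frame the endpoint nearer the anchor point (the stimulus
#' target, which is known to be at the head) is set as head; the orientation
#' is propagated forward and backward by choosing, frame to frame, the
#' endpoint assignment that minimizes head displacement. Anchors whose two
#' endpoints are equidistant to the target (within `tie_tol_px`) trigger an
#' annotation request instead of a silent choice, as do propagation jumps
#' above `jump_frac` of the body length.
#'
#' @param skeletons list of `worm_skeleton` (complex frames carried over
#'   unchanged).
#' @param anchors data.frame with `frame`, `x`, `y` (same pixel coordinates
#'   as the skeletons): stimulus targets and/or user-annotated head points.
#' @param tie_tol_px tie tolerance at anchors (px).
#' @param jump_frac displacement (fraction of body length) above which a
#'   frame is recorded for review.
#' @return list: `skeletons` (oriented), `flipped` (logical per frame),
#'   `requests` (data.frame frame/reason of annotation requests).
#' @export
correct_head_tail <- function(skeletons, anchors, tie_tol_px = 1,
                              jump_frac = 0.5) {
  n <- length(skeletons)
  if (is.null(anchors) || nrow(anchors) == 0L)
    stop("no stimulus anchor or annotated head frame available; head-tail orientation requires annotation")
  requests <- list()
  usable <- list()
  for (j in seq_len(nrow(anchors))) {
    fr <- anchors$frame[j]
    s <- skeletons[[fr]]
    if (is.null(s$points) || isTRUE(s$complex)) {
      requests[[length(requests) + 1L]] <-
        data.frame(frame = fr, reason = "anchor frame is complex")
      next
    }
    N <- nrow(s$points)
    d1 <- sqrt(sum((s$points[1, ] - c(anchors$x[j], anchors$y[j]))^2))
    dN <- sqrt(sum((s$points[N, ] - c(anchors$x[j], anchors$y[j]))^2))
    if (abs(d1 - dN) < tie_tol_px) {
      requests[[length(requests) + 1L]] <-
        data.frame(frame = fr, reason = "anchor equidistant to both endpoints")
      next
    }
    usable[[length(usable) + 1L]] <- list(frame = fr, flip = dN < d1)
  }
  if (!length(usable))
    stop("no usable anchor (all ties or complex); annotate a head frame")
  anchor_frames <- vapply(usable, `[[`, 0, "frame")
  flips <- rep(NA, n)
  # ownership: each frame belongs to the nearest usable anchor
  owner <- vapply(seq_len(n), function(i)
    which.min(abs(anchor_frames - i)), 0L)
  flip_pts <- function(s, flip) {
    if (flip && !is.null(s$points)) {
      s$points <- s$points[rev(seq_len(nrow(s$points))), , drop = FALSE]
    }
    s$oriented <- TRUE
    s
  }
  out <- skeletons
  for (j in seq_along(usable)) {
    a <- usable[[j]]$frame
    mine <- which(owner == j)
    flips[a] <- usable[[j]]$flip
    out[[a]] <- flip_pts(skeletons[[a]], flips[a])
    for (dir in c(1L, -1L)) {
      prev_head <- out[[a]]$points[1, ]
      prev_len <- out[[a]]$length_px
      i <- a + dir
      while (i >= 1L && i <= n && i %in% mine) {
        s <- skeletons[[i]]
        if (is.null(s$points) || isTRUE(s$complex)) {
          out[[i]] <- s
          i <- i + dir
          next
        }
        N <- nrow(s$points)
        d_keep <- sqrt(sum((s$points[1, ] - prev_head)^2))
        d_flip <- sqrt(sum((s$points[N, ] - prev_head)^2))
        flips[i] <- d_flip < d_keep
        if (min(d_keep, d_flip) > jump_frac * (prev_len %||% s$length_px))
          requests[[length(requests) + 1L]] <-
            data.frame(frame = i, reason = "head jump exceeds threshold")
        out[[i]] <- flip_pts(s, flips[i])
        prev_head <- out[[i]]$points[1, ]
        prev_len <- out[[i]]$length_px
        i <- i + dir
      }
    }
  }
  list(skeletons = out, flipped = flips,
       requests = if (length(requests)) do.call(rbind, requests)
       else data.frame(frame = integer(0), reason = character(0)))
}
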