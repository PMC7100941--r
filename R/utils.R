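# Shared geometry / signal helpers.

#' Unwrap a phase series
#'
#' Removes jumps larger than half a period from a sampled angle series so the
#' result is continuous. `NA` runs are skipped and the offset is carried
#' across them.
#'
#' @param x numeric vector of angles.
#' @param period period of the angle variable (default `2*pi`; use 1 for
#'   phases expressed in cycles).
#' @return numeric vector, same length as `x`, unwrapped.
#' @export
unwrap_phase <- function(x, period = 2 * pi) {
  ok <- which(!is.na(x))
  if (length(ok) < 2L) return(x)
  v <- x[ok]
  d <- diff(v)
  corr <- -period * round(d / period)
  v <- v + c(0, cumsum(corr))
  x[ok] <- v
  x
}

#' Resample a polyline to n points equally spaced in arc length
#'
#' @param pts m x 2 matrix of ordered points.
#' @param n number of output points (endpoints preserved).
#' @return n x 2 matrix.
#' @export
resample_polyline <- function(pts, n) {
  pts <- as.matrix(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) return(matrix(rep(pts[1, ], each = n), ncol = 2))
  # collapse duplicated arc-length knots
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; pts <- pts[keep, , drop = FALSE]
  si <- seq(0, L, length.out = n)
  cbind(stats::approx(s, pts[, 1], xout = si)$y,
        stats::approx(s, pts[, 2], xout = si)$y)
}

#' Arc length of a polyline
#' @param pts m x 2 matrix.
#' @return total length (same units as coordinates).
#' @export
polyline_length <- function(pts) {
  sum(sqrt(rowSums(diff(as.matrix(pts))^2)))
}

#' Tangent-angle profile of a skeleton
#'
#' Angles of the N-1 segments of an N-point midline, unwrapped along the
#' body so the profile is continuous.
#'
#' @param skel N x 2 matrix, head at row 1.
#' @return numeric vector of length N-1 (radians).
#' @export
tangent_angles <- function(skel) {
  d <- diff(as.matrix(skel))
  unwrap_phase(atan2(d[, 2], d[, 1]))
}

#' Rebuild a midline from a tangent-angle profile
#'
#' Inverse of [tangent_angles()]: integrates M segment angles into an
#' (M+1)-point curve of total arc length `length_out`, centred so its mean
#' point sits at `centroid`.
#'
#' @param angles M segment angles (radians).
#' @param length_out total arc length of the output curve.
#' @param centroid length-2 numeric, mean point of the output curve.
#' @return (M+1) x 2 matrix.
#' @export
angles_to_midline <- function(angles, length_out, centroid = c(0, 0)) {
  ds <- length_out / length(angles)
  x <- c(0, cumsum(ds * cos(angles)))
  y <- c(0, cumsum(ds * sin(angles)))
  p <- cbind(x, y)
  sweep(p, 2, colMeans(p) - centroid)
}

# running median with edge padding (odd window)
running_median <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  if (n == 0L) return(x)
  if (k >= n) return(rep(stats::median(x, na.rm = TRUE), n))
  stats::runmed(x, k, endrule = "median")
}

# linear interpolation over interior NA runs; ends held at nearest value
fill_na_linear <- function(x) {
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L) return(x)
  out <- stats::approx(ok, x[ok], xout = seq_len(n), rule = 2)$y
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
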