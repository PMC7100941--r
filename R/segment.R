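# Single-worm segmentation: threshold polling -> front-propagation
# refinement -> loop-aware hole filling.

# ---- histogram threshold methods -------------------------------------------
# Each returns a threshold in [0, 1] for an image scaled to [0, 1].
# Otsu comes from EBImage; triangle, mean and isodata are the standard
# histogram formulations.

thr_otsu <- function(img) EBImage::otsu(img, range = c(0, 1), levels = 256)

thr_mean <- function(img) mean(img)

thr_isodata <- function(img) {
  thr <- mean(img)
  for (i in 1:100) {
    lo <- img[img <= thr]; hi <- img[img > thr]
    if (!length(lo) || !length(hi)) break
    new <- (mean(lo) + mean(hi)) / 2
    if (abs(new - thr) < 1e-6) break
    thr <- new
  }
  thr
}

thr_triangle <- function(img) {
  h <- graphics::hist(img, breaks = seq(0, 1, length.out = 257),
                      plot = FALSE)$counts
  mids <- (seq(0, 1, length.out = 257)[-257] + 1 / 512)
  pk <- which.max(h)
  # far histogram end on the longer tail side
  far <- if ((256 - pk) > (pk - 1)) max(which(h > 0)) else min(which(h > 0))
  idx <- if (far > pk) pk:far else far:pk
  x1 <- pk; y1 <- h[pk]; x2 <- far; y2 <- h[far]
  # perpendicular distance of histogram points to the peak-to-end chord
  d <- abs((y2 - y1) * idx - (x2 - x1) * h[idx] + x2 * y1 - y2 * x1)
  mids[idx[which.max(d)]]
}

.threshold_panel <- list(otsu = thr_otsu, triangle = thr_triangle,
                         mean = thr_mean, isodata = thr_isodata)

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0L) return(list(mask = mask & FALSE, area = 0L,
                                  n_components = 0L))
  tab <- tabulate(lab[lab > 0L])
  best <- which.max(tab)
  list(mask = lab == best, area = tab[best], n_components = length(tab))
}

#' Poll histogram threshold methods for the best worm segmentation
#'
#' Evaluates a panel of histogram-based thresholding algorithms (Otsu,
#' triangle, mean, isodata by default) and keeps the candidate whose largest
#' connected component has area closest to the expected worm area. All
#' candidates are reported for audit.
#'
#' @param img grayscale matrix in [0, 1].
#' @param expected_area expected worm area in pixels (e.g. the running
#'   median over an initialization window, seeded from a length/width prior).
#' @param polarity `"dark"` (worm darker than field, default) or `"light"`.
#' @param panel named list of threshold functions; defaults to the built-in
#'   four-method panel.
#' @param min_area components smaller than this are treated as "no object".
#' @param max_area_factor candidates whose largest component exceeds
#'   `max_area_factor * expected_area` are implausible (e.g. thresholded
#'   background noise) and rejected.
#' @param min_range images whose intensity range is below this carry no
#'   object worth thresholding.
#' @return list: `mask` (largest component of the winning candidate),
#'   `threshold`, `method`, `flag` (`"ok"`/`"failed"`), and `candidates`
#'   data.frame (method, threshold, area, n_components).
#' @export
poll_thresholds <- function(img, expected_area, polarity = c("dark", "light"),
                            panel = .threshold_panel, min_area = 15L,
                            max_area_factor = 4, min_range = 0.08) {
  polarity <- match.arg(polarity)
  rng <- range(img)
  if (diff(rng) <= 0)
    return(list(mask = NULL, threshold = NA_real_, method = NA_character_,
                flag = "failed", reason = "constant image",
                candidates = data.frame()))
  if (diff(rng) < min_range)
    return(list(mask = NULL, threshold = NA_real_, method = NA_character_,
                flag = "failed", reason = "no object",
                candidates = data.frame()))
  cand <- lapply(names(panel), function(m) {
    thr <- panel[[m]](img)
    mask <- if (polarity == "dark") img < thr else img > thr
    comp <- largest_component(mask)
    list(method = m, threshold = thr, comp = comp)
  })
  tab <- data.frame(
    method = vapply(cand, `[[`, "", "method"),
    threshold = vapply(cand, `[[`, 0, "threshold"),
    area = vapply(cand, function(x) as.integer(x$comp$area), 0L),
    n_components = vapply(cand, function(x) x$comp$n_components, 0L))
  ok <- tab$area >= min_area & tab$area <= max_area_factor * expected_area
  if (!any(ok))
    return(list(mask = NULL, threshold = NA_real_, method = NA_character_,
                flag = "failed", reason = "no object", candidates = tab))
  score <- abs(tab$area - expected_area)
  score[!ok] <- Inf
  best <- which.min(score)
  list(mask = cand[[best]]$comp$mask, threshold = tab$threshold[best],
       method = tab$method[best], flag = "ok", reason = NA_character_,
       candidates = tab)
}

#' Refine a seed mask by intensity-driven front propagation
#'
#' Propagates a front outward from the high-confidence core of the seed with
#' local speed `1 / (1 + ((I - mu)/sigma)^2)`, where `mu`/`sigma` are the
#' seed-interior intensity statistics; pixels whose arrival time stays below
#' `time_threshold` form the refined mask. Arrival times are computed as
#' shortest paths on the 8-connected pixel lattice (edge cost = mean
#' reciprocal speed of the endpoints, diagonal steps scaled by sqrt(2)), the
#' discrete counterpart of the fast-marching arrival-time solution. The
#' correction is bounded: growth is capped at `max_grow` pixels from the
#' seed, and only seed pixels of outlying intensity can be dropped.
#'
#' @param img grayscale matrix in [0, 1].
#' @param seed logical seed mask (>= 1 foreground pixel).
#' @param time_threshold arrival-time cutoff (units of reciprocal speed).
#' @param max_grow maximum growth distance from the seed (pixels).
#' @return logical refined mask (largest component).
#' @export
refine_fast_marching <- function(img, seed, time_threshold = 20,
                                 max_grow = 12L) {
  if (is.null(seed) || sum(seed) == 0L) stop("seed mask is empty")
  H <- nrow(img); W <- ncol(img)
  # high-confidence core: seed pixels within 2.5 robust sd of the seed median
  iv <- img[seed]
  mu <- stats::median(iv)
  sg <- max(stats::mad(iv), 1e-3)
  core <- seed & abs(img - mu) < 2.5 * sg
  if (sum(core) == 0L) core <- seed
  # restrict work to a window around the seed
  idx <- which(seed, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - max_grow - 2L)
  r1 <- min(H, max(idx[, 1]) + max_grow + 2L)
  c0 <- max(1L, min(idx[, 2]) - max_grow - 2L)
  c1 <- min(W, max(idx[, 2]) + max_grow + 2L)
  sub <- img[r0:r1, c0:c1, drop = FALSE]
  subcore <- core[r0:r1, c0:c1, drop = FALSE]
  h <- nrow(sub); w <- ncol(sub)
  cost <- 1 + ((sub - mu) / sg)^2   # reciprocal speed
  # 8-neighbour lattice graph
  id <- matrix(seq_len(h * w), h, w)
  edges <- list(); wts <- list()
  add <- function(a, b, scale) {
    edges[[length(edges) + 1L]] <<- rbind(as.vector(a), as.vector(b))
    wts[[length(wts) + 1L]] <<-
      scale * (cost[as.vector(a)] + cost[as.vector(b)]) / 2
  }
  add(id[-h, ], id[-1, ], 1)                 # vertical
  add(id[, -w], id[, -1], 1)                 # horizontal
  add(id[-h, -w], id[-1, -1], sqrt(2))       # diag down-right
  add(id[-1, -w], id[-h, -1], sqrt(2))       # diag up-right
  g <- igraph::make_graph(edges = as.vector(rbind(
    do.call(cbind, edges)[1, ], do.call(cbind, edges)[2, ])),
    n = h * w, directed = FALSE)
  src <- h * w + 1L
  g <- igraph::add_vertices(g, 1L)
  core_ids <- which(as.vector(subcore))
  g <- igraph::add_edges(g, as.vector(rbind(src, core_ids)))
  allw <- c(unlist(wts), rep(0, length(core_ids)))
  d <- as.vector(igraph::distances(g, v = src, weights = allw))[seq_len(h * w)]
  refined_sub <- matrix(d <= time_threshold, h, w)
  # cap growth distance from the original seed
  grow_ok <- EBImage::dilate(seed[r0:r1, c0:c1, drop = FALSE] * 1,
                             EBImage::makeBrush(2L * max_grow + 1L,
                                                shape = "box")) > 0
  refined_sub <- refined_sub & grow_ok
  refined <- matrix(FALSE, H, W)
  refined[r0:r1, c0:c1] <- refined_sub
  largest_component(refined)$mask
}

#' Fill interior holes, preserving loop centres
#'
#' Fills holes in the body mask except those matching the centre of a looped
#' (self-occluding) worm: a preserved hole must have area between
#' `min_frac` and `max_frac` of the body area and solidity above
#' `min_solidity`. Smaller holes are treated as noise, larger ones as
#' segmentation failures.
#'
#' @param mask logical body mask (one main component).
#' @param min_frac,max_frac hole-area bounds as fractions of body area.
#' @param min_solidity minimum hole solidity (area / convex hull area).
#' @return list: `mask` (filled), `holes` data.frame audit of every interior
#'   hole (area, solidity, preserved).
#' @export
fill_holes_keep_loops <- function(mask, min_frac = 0.02, max_frac = 0.40,
                                  min_solidity = 0.7) {
  body_area <- sum(mask)
  comp <- EBImage::bwlabel(!mask)
  H <- nrow(mask); W <- ncol(mask)
  border_labs <- unique(c(comp[1, ], comp[H, ], comp[, 1], comp[, W]))
  labs <- setdiff(seq_len(max(comp)), c(0L, border_labs))
  if (!length(labs))
    return(list(mask = mask,
                holes = data.frame(area = integer(0), solidity = numeric(0),
                                   preserved = logical(0))))
  rows <- lapply(labs, function(l) {
    px <- which(comp == l, arr.ind = TRUE)
    area <- nrow(px)
    sol <- if (area >= 3L) {
      ch <- grDevices::chull(px)
      hull <- px[ch, , drop = FALSE]
      ha <- abs(sum(hull[, 1] * c(hull[-1, 2], hull[1, 2]) -
                    hull[, 2] * c(hull[-1, 1], hull[1, 1]))) / 2
      # pixel-area convex hull: polygon area underestimates for small blobs
      area / max(ha + nrow(hull) / 2 + 1, area)
    } else 1
    keep <- area >= min_frac * body_area && area <= max_frac * body_area &&
      sol > min_solidity
    data.frame(area = area, solidity = sol, preserved = keep)
  })
  holes <- do.call(rbind, rows)
  out <- mask
  for (j in seq_along(labs))
    if (!holes$preserved[j]) out[comp == labs[j]] <- TRUE
  list(mask = out, holes = holes)
}

#' Segment one frame through the full chain
#'
#' Threshold polling, front-propagation refinement, then loop-aware hole
#' filling, with a quality flag.
#'
#' @param img grayscale matrix in [0, 1].
#' @param expected_area expected worm area (px).
#' @param polarity see [poll_thresholds()].
#' @param area_bounds acceptable area range as fractions of `expected_area`.
#' @param refine run the front-propagation refinement (default TRUE).
#' @return list: `mask`, `flag` (`ok`/`suspect`/`failed`), `method`,
#'   `threshold`, `area`, `holes` audit table.
#' @export
segment_frame <- function(img, expected_area, polarity = "dark",
                          area_bounds = c(0.4, 2.5), refine = TRUE) {
  polled <- poll_thresholds(img, expected_area, polarity)
  if (polled$flag == "failed")
    return(list(mask = NULL, flag = "failed", reason = polled$reason,
                method = polled$method, threshold = polled$threshold,
                area = 0L, holes = NULL))
  mask <- polled$mask
  if (refine) mask <- refine_fast_marching(img, mask)
  filled <- fill_holes_keep_loops(mask)
  area <- sum(filled$mask)
  flag <- if (area >= area_bounds[1] * expected_area &&
              area <= area_bounds[2] * expected_area) "ok" else "suspect"
  list(mask = filled$mask, flag = flag, reason = NA_character_,
       method = polled$method, threshold = polled$threshold,
       area = area, holes = filled$holes)
}

#' Segment a whole recording
#'
#' Applies [segment_frame()] to every frame. The expected area starts from a
#' worm length/width prior and is replaced by the running median of accepted
#' areas once an initialization window has been seen.
#'
#' @param rec `synthetic_recording` (or any list with `$stack`,
#'   `$pixel_size_mm`).
#' @param worm_length_mm,worm_width_mm prior body dimensions for the initial
#'   expected area.
#' @param init_window frames used to establish the area median.
#' @param ... passed to [segment_frame()].
#' @return list: `masks` (list, NULL where failed), `quality` data.frame
#'   (frame, method, threshold, area, n_holes_kept, flag).
#' @export
segment_recording <- function(rec, worm_length_mm = NULL,
                              worm_width_mm = 0.08, init_window = 25L, ...) {
  px <- rec$pixel_size_mm
  L <- worm_length_mm %||% rec$truth$schedule$worm_length_mm %||% 1
  expected <- 0.85 * L * worm_width_mm / px^2  # tapered body correction
  n <- length(rec$stack)
  masks <- vector("list", n)
  qual <- vector("list", n)
  areas <- numeric(0)
  for (i in seq_len(n)) {
    exp_i <- if (length(areas) >= init_window)
      stats::median(areas) else expected
    sf <- segment_frame(rec$stack[[i]], exp_i, ...)
    masks[[i]] <- sf$mask
    if (sf$flag == "ok") areas <- c(areas, sf$area)
    qual[[i]] <- data.frame(
      frame = i, method = sf$method %||% NA_character_,
      threshold = sf$threshold %||% NA_real_, area = sf$area,
      n_holes_kept = if (is.null(sf$holes)) 0L else sum(sf$holes$preserved),
      flag = sf$flag)
  }
  list(masks = masks, quality = do.call(rbind, qual))
}

#' Binary-mask centroid in frame pixel coordinates
#' @param mask logical matrix (rows = y, cols = x).
#' @return length-2 numeric (x, y) or `c(NA, NA)` for an empty mask.
#' @export
mask_centroid <- function(mask) {
  if (is.null(mask) || !sum(mask)) return(c(NA_real_, NA_real_))
  px <- which(mask, arr.ind = TRUE)
  c(mean(px[, 2]), mean(px[, 1]))
}
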