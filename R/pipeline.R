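# Pipeline orchestration: configuration, the recording-to-ethogram chain,
# cohort summaries, and run manifests.

#' Pipeline configuration
#'
#' Defaults are the study's printed analysis constants: pause below 0.02
#' cycles/s, turn below half the average head-tail distance, minimum
#' behavioral segment 0.25 s, spike threshold 0.18 (per-frame change in
#' phase velocity, cycles/s).
#'
#' @param frame_rate Hz (NULL = take from the recording).
#' @param pixel_size_mm camera scale (NULL = take from the recording).
#' @param pause_thr_cyc_s pause threshold on |omega|.
#' @param turn_frac turn threshold as a fraction of average head-tail
#'   distance.
#' @param min_segment_s minimum ethogram segment duration.
#' @param spike_thr spike-removal jump threshold.
#' @param spike_units `"per_frame"` or `"per_second"`.
#' @param target_fraction targeted anterior body fraction.
#' @param n_points skeleton points.
#' @param max_gap_s longest complex run bridged by interpolation.
#' @param refine_segmentation run front-propagation refinement per frame.
#' @param seed RNG seed recorded with the run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(frame_rate = NULL, pixel_size_mm = NULL,
                            pause_thr_cyc_s = 0.02, turn_frac = 0.5,
                            min_segment_s = 0.25, spike_thr = 0.18,
                            spike_units = "per_frame",
                            target_fraction = 0.2, n_points = 49L,
                            max_gap_s = 2, refine_segmentation = TRUE,
                            seed = 1L) {
  cfg <- list(frame_rate = frame_rate, pixel_size_mm = pixel_size_mm,
              pause_thr_cyc_s = pause_thr_cyc_s, turn_frac = turn_frac,
              min_segment_s = min_segment_s, spike_thr = spike_thr,
              spike_units = spike_units, target_fraction = target_fraction,
              n_points = as.integer(n_points), max_gap_s = max_gap_s,
              refine_segmentation = refine_segmentation,
              seed = as.integer(seed))
  for (nm in c("pause_thr_cyc_s", "turn_frac", "min_segment_s",
               "spike_thr", "target_fraction", "max_gap_s"))
    stopifnot_scalar(cfg[[nm]], nm)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param config `pipeline_config`.
#' @param path file path.
#' @return `read_config` returns a `pipeline_config` identical to the one
#'   written.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Kinematics and ethogram from a skeleton series
#'
#' The shared analysis core: eigenworm projection, posture-space repair of
#' complex frames, phase and phase velocity with spike removal, head-tail
#' distances, state flagging and minimum-duration enforcement. Used both on
#' skeletons measured from images and directly on ground-truth skeletons.
#'
#' @param skeletons N x 2 x T array (consistently oriented, head first) or
#'   list of `worm_skeleton` (complex frames allowed).
#' @param frame_rate Hz.
#' @param basis `eigenworm_basis` (default [reference_eigenbasis()]).
#' @param config `pipeline_config`.
#' @param centroid_mm optional T x 2 world centroids (for velocity and
#'   escape distance); default from the skeleton means.
#' @param turn_candidates optional logical per-frame extra turn evidence.
#' @return list: `kinematics` (per-frame data.frame), `ethogram`,
#'   `modes` (T x 4), `basis`.
#' @export
analyze_skeleton_series <- function(skeletons, frame_rate,
                                    basis = NULL,
                                    config = pipeline_config(),
                                    centroid_mm = NULL,
                                    turn_candidates = NULL) {
  basis <- basis %||% reference_eigenbasis(
    if (is.array(skeletons)) dim(skeletons)[1] else config$n_points)
  pr <- project_series(skeletons, basis)
  n <- nrow(pr$modes)
  complex_fr <- which(!is.finite(pr$modes[, 1]))
  ip <- interpolate_complex(pr$modes, complex_fr, frame_rate,
                            max_gap_s = config$max_gap_s)
  ph <- posture_phase(ip$modes)
  omega <- phase_velocity(ph$phi_cycles, frame_rate)
  sp <- remove_phase_spikes(omega, frame_rate, threshold = config$spike_thr,
                            units = config$spike_units)
  headtail <- if (is.array(skeletons)) {
    N <- dim(skeletons)[1]
    sqrt((skeletons[1, 1, ] - skeletons[N, 1, ])^2 +
         (skeletons[1, 2, ] - skeletons[N, 2, ])^2)
  } else vapply(skeletons, function(s) {
    if (is.null(s$points) || isTRUE(s$complex)) return(NA_real_)
    sqrt(sum((s$points[1, ] - s$points[nrow(s$points), ])^2))
  }, 0)
  states <- flag_states(sp$omega, headtail,
                        pause_thr = config$pause_thr_cyc_s,
                        turn_frac = config$turn_frac,
                        turn_candidates = turn_candidates)
  eth <- enforce_min_duration(states, frame_rate,
                              min_s = config$min_segment_s)
  if (is.null(centroid_mm)) {
    centroid_mm <- if (is.array(skeletons))
      t(apply(skeletons, 3, colMeans))
    else t(vapply(skeletons, function(s)
      if (is.null(s$points)) c(NA_real_, NA_real_)
      else colMeans(s$points), numeric(2)))
  }
  kin <- data.frame(frame = seq_len(n),
                    time_s = (seq_len(n) - 1L) / frame_rate,
                    a1 = ip$modes[, 1], a2 = ip$modes[, 2],
                    a3 = ip$modes[, 3], a4 = ip$modes[, 4],
                    phi_cycles = ph$phi_cycles, omega_cyc_s = sp$omega,
                    removed_flag = sp$removed, removal_reason = sp$reason,
                    headtail = headtail, state_raw = states,
                    state = eth$states,
                    centroid_x = centroid_mm[, 1],
                    centroid_y = centroid_mm[, 2])
  list(kinematics = kin, ethogram = eth, modes = ip$modes, basis = basis)
}

#' Run the full analysis pipeline on a recording
#'
#' Stages execute in order: segmentation, skeletonization and head-tail
#' correction, stage registration, kinematics, ethogram. All intermediate
#' artifacts are persisted under `out_dir` together with a run manifest
#' (config snapshot, file checksums, per-stage tallies). Deterministic for
#' a fixed recording and config.
#'
#' @param rec `synthetic_recording` (in memory, or from [read_recording()]).
#' @param config `pipeline_config`.
#' @param out_dir output directory (NULL = nothing persisted).
#' @return list: `kinematics` data.frame (incl. world-mm centroid and
#'   velocities), `ethogram`, `segment_quality`, `stage` trajectory,
#'   `skeletons` (oriented list), `orientation_requests`, `manifest`.
#' @export
run_pipeline <- function(rec, config = pipeline_config(), out_dir = NULL) {
  fps <- config$frame_rate %||% rec$frame_rate
  px <- config$pixel_size_mm %||% rec$pixel_size_mm
  n <- length(rec$stack)
  dim_hw <- dim(rec$stack[[1]])
  warnings <- character(0)

  # 1. segmentation
  seg <- segment_recording(rec, refine = config$refine_segmentation)
  masks <- seg$masks

  # 2. skeletons
  skels <- vector("list", n)
  for (i in seq_len(n)) {
    skels[[i]] <- if (is.null(masks[[i]]) || seg$quality$flag[i] == "failed")
      structure(list(points = NULL, length_px = NA_real_, complex = TRUE,
                     oriented = FALSE), class = "worm_skeleton")
    else midline_simple(masks[[i]], n_points = config$n_points)
  }
  complex_idx <- flag_complex_frames(
    skels, extra = seg$quality$n_holes_kept > 0)
  for (i in complex_idx) skels[[i]]$complex <- TRUE

  # 3. stage registration (image-estimated, anchored at the reported start)
  shifts <- register_stack(rec$stack, masks, lags = 1:3)
  start_mm <- c(rec$stage_reported$stage_x_mm[1],
                rec$stage_reported$stage_y_mm[1])
  stage <- integrate_stage_motion(shifts, start_mm,
                                  simple_calibration(px), sign = -1)

  # 4. head-tail correction from stimulus anchors
  if (is.null(rec$stimuli) || nrow(rec$stimuli) == 0L)
    stop("recording carries no stimulus events; head-tail orientation requires an anchor")
  anchors <- do.call(rbind, lapply(seq_len(nrow(rec$stimuli)), function(j) {
    fr <- rec$stimuli$frame[j]
    p <- c(rec$stimuli$target_x_mm[j], rec$stimuli$target_y_mm[j])
    st <- c(stage$x_mm[fr], stage$y_mm[fr])
    ctr <- c((dim_hw[2] + 1) / 2, (dim_hw[1] + 1) / 2)
    px_pt <- (p - st) / px + ctr
    data.frame(frame = fr, x = px_pt[1], y = px_pt[2])
  }))
  ht <- correct_head_tail(skels, anchors)
  skels <- ht$skeletons

  # 5. kinematics + ethogram (world-mm centroids via the stage trajectory)
  ctr_px <- t(vapply(masks, function(m)
    if (is.null(m)) c(NA_real_, NA_real_) else mask_centroid(m), numeric(2)))
  ctr_mm <- cbind((ctr_px[, 1] - (dim_hw[2] + 1) / 2) * px + stage$x_mm,
                  (ctr_px[, 2] - (dim_hw[1] + 1) / 2) * px + stage$y_mm)
  ctr_sm <- smooth_centroid(ctr_mm, time_s = rec$timestamps)
  turn_cand <- seg$quality$n_holes_kept > 0
  ana <- analyze_skeleton_series(skels, fps, config = config,
                                 centroid_mm = ctr_sm,
                                 turn_candidates = turn_cand)
  head_px <- t(vapply(skels, function(s)
    if (is.null(s$points) || !isTRUE(s$oriented)) c(NA_real_, NA_real_)
    else s$points[1, ], numeric(2)))
  head_mm <- cbind((head_px[, 1] - (dim_hw[2] + 1) / 2) * px + stage$x_mm,
                   (head_px[, 2] - (dim_hw[1] + 1) / 2) * px + stage$y_mm)
  tv <- translational_velocity(ctr_sm, head_mm, fps)
  kin <- cbind(ana$kinematics[, setdiff(names(ana$kinematics),
                                        c("centroid_x", "centroid_y"))],
               data.frame(centroid_x_mm = ctr_sm[, 1],
                          centroid_y_mm = ctr_sm[, 2]),
               tv)
  kin$headtail_mm <- kin$headtail * px
  kin$time_s <- rec$timestamps

  out <- list(kinematics = kin, ethogram = ana$ethogram,
              segment_quality = seg$quality, stage = stage,
              skeletons = skels, orientation_requests = ht$requests,
              stimuli = rec$stimuli, frame_rate = fps,
              pixel_size_mm = px, config = config)
  if (!is.null(out_dir)) out$manifest <- persist_run(out, rec, out_dir)
  out
}

# write all artifacts of a run and build the manifest
persist_run <- function(run, rec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }
  wcsv(run$kinematics, "kinematics.csv")
  wcsv(data.frame(frame = seq_along(run$ethogram$states),
                  time_s = run$kinematics$time_s,
                  state = run$ethogram$states), "ethogram.csv")
  wcsv(run$ethogram$segments, "segments.csv")
  wcsv(run$segment_quality, "segment_quality.csv")
  wcsv(run$stage, "stage_trajectory.csv")
  sk <- do.call(rbind, lapply(seq_along(run$skeletons), function(i) {
    s <- run$skeletons[[i]]
    if (is.null(s$points)) return(NULL)
    data.frame(frame = i, point = seq_len(nrow(s$points)),
               x_px = s$points[, 1], y_px = s$points[, 2])
  }))
  if (!is.null(sk)) wcsv(sk, "skeletons.csv")
  cfgp <- file.path(out_dir, "config.yaml")
  write_config(run$config, cfgp)
  paths[[length(paths) + 1L]] <- cfgp
  jsonlite::write_json(run$stimuli, file.path(out_dir, "stimuli.json"),
                       auto_unbox = TRUE, digits = NA)
  paths[[length(paths) + 1L]] <- file.path(out_dir, "stimuli.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("wormescape")),
    n_frames = length(run$skeletons),
    n_complex = sum(vapply(run$skeletons, function(s)
      isTRUE(s$complex), TRUE)),
    n_removed = sum(run$kinematics$removed_flag, na.rm = TRUE),
    n_segments = nrow(run$ethogram$segments),
    n_orientation_requests = nrow(run$orientation_requests),
    config = unclass(run$config),
    outputs = lapply(stats::setNames(paths, basename(unlist(paths))),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Summarize a cohort of completed runs around their stimuli
#'
#' Builds the per-animal traces from each run, aligns them to the stimulus
#' events, and writes population summary CSVs (and figures) per group.
#'
#' @param runs list of [run_pipeline()] results (each with stimuli).
#' @param labels optional per-run group labels (default one group).
#' @param window,step alignment window and grid step (s).
#' @param out_dir optional output directory for CSVs and figures.
#' @return named list of `population_summary` per group.
#' @export
summarize_cohort <- function(runs, labels = NULL, window = c(-5, 30),
                             step = 0.05, out_dir = NULL) {
  if (!length(runs)) stop("empty cohort")
  labels <- labels %||% rep("all", length(runs))
  fps <- vapply(runs, function(r) r$frame_rate, 0)
  animals <- lapply(runs, function(r) {
    k <- r$kinematics
    list(time_s = k$time_s, states = r$ethogram$states,
         omega = k$omega_cyc_s,
         centroid_mm = cbind(k$centroid_x_mm %||% k$centroid_x,
                             k$centroid_y_mm %||% k$centroid_y),
         events = r$stimuli$time_s)
  })
  out <- list()
  for (g in unique(labels)) {
    sel <- which(labels == g)
    out[[g]] <- align_to_stimulus(animals[sel], window = window,
                                  step = step)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(out[[g]]$grid,
                       file.path(out_dir, sprintf("population_%s.csv", g)),
                       row.names = FALSE)
      grDevices::png(file.path(out_dir, sprintf("fractions_%s.png", g)),
                     width = 900, height = 600)
      plot_state_fractions(out[[g]])
      grDevices::dev.off()
      grDevices::png(file.path(out_dir, sprintf("ethogram_%s.png", g)),
                     width = 900, height = 600)
      plot_ethogram_raster(out[[g]])
      grDevices::dev.off()
    }
  }
  out
}

#' Plot population state fractions around the stimulus
#' @param summary `population_summary`.
#' @export
plot_state_fractions <- function(summary) {
  g <- summary$grid
  graphics::matplot(g$t_rel_s,
                    cbind(g$frac_forward, g$frac_reverse, g$frac_pause,
                          g$frac_turn),
                    type = "l", lty = 1, lwd = 2,
                    col = c("#1b9e77", "#d95f02", "#7570b3", "#e7298a"),
                    xlab = "time relative to stimulus (s)",
                    ylab = "fraction of animals", ylim = c(0, 1))
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", c("forward", "reverse", "pause", "turn"),
                   lty = 1, lwd = 2,
                   col = c("#1b9e77", "#d95f02", "#7570b3", "#e7298a"))
}

#' Ethogram raster of aligned traces
#' @param summary `population_summary`.
#' @export
plot_ethogram_raster <- function(summary) {
  S <- summary$traces$states
  lev <- c("forward", "reverse", "pause", "turn", "missing")
  M <- matrix(match(S, lev), nrow(S), ncol(S))
  graphics::image(summary$grid$t_rel_s, seq_len(nrow(S)), t(M),
                  col = c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
                          "grey85"),
                  xlab = "time relative to stimulus (s)", ylab = "animal",
                  useRaster = TRUE)
  graphics::abline(v = 0, lty = 3)
}
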