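# The resolution-zoom closed loop: acquire coarse, score z-thirds against
# the normative sample, zoom the field of view into the most outlying third,
# double the resolution, repeat; keep the full trace and the acquired
# volumes (the "composite" image).

#' Pick the most outlying region
#'
#' @param scores list of three `subvolume_score`s (or a numeric vector of
#'   three distances).
#' @return The 0-based index of the region with the highest outlier
#'   distance; ties break to the lowest index.
#' @export
pick_region <- function(scores) {
  d <- if (is.numeric(scores)) scores
       else vapply(scores, function(s) s$distance, numeric(1))
  if (length(d) != 3L || any(!is.finite(d)))
    stop("`scores` must be three finite distances")
  which.max(d) - 1L
}

#' Stop/continue decision
#'
#' Decides whether sufficient data have been collected: scanning continues
#' while the outlier distance is at or above the threshold (boundary
#' inclusive -- scanning more on ambiguity is the conservative choice).
#'
#' @param score current outlier distance.
#' @param threshold decision threshold (> 0), in the same (MAD) units.
#' @return `"CONTINUE"` or `"STOP"`.
#' @export
stop_or_continue <- function(score, threshold) {
  if (!is.finite(threshold) || threshold <= 0) stop("`threshold` must be > 0")
  if (score >= threshold) "CONTINUE" else "STOP"
}

#' Run the multi-resolution zoom loop on one subject
#'
#' At each resolution the subject and every normative subject are
#' "re-acquired" at the current field of view, the three z-thirds are scored
#' by robust outlier distance against the normative per-third summaries, and
#' the next (finer) scan covers only the most outlying third. Default
#' schedule: 4, 2, 1 mm (the resolution doubles, i.e. the voxel halves, at
#' each of three iterations). The loop stops early, with the reason
#' recorded, if the next field of view would span fewer than 3 z-voxels at
#' the next resolution.
#'
#' @param truth the subject's ground-truth `volume_grid` (finest resolution).
#' @param normative_truths list of >= 2 ground-truth `volume_grid`s for the
#'   normative subjects.
#' @param resolutions_mm strictly decreasing isotropic voxel sizes, mm.
#' @param threshold stop/continue threshold on the running maximum distance
#'   (MAD units); the decision is recorded per step, the loop itself always
#'   zooms (matching an offline simulation where all scans are available).
#' @param seed seed (acquisition here is noise-free, so this only matters
#'   if acquisition noise is enabled via `noise_sd0`).
#' @param noise_sd0 optional acquisition noise passed to [acquire()].
#' @return A `composite_image`: list with `steps` (per-iteration records:
#'   `iteration`, `voxel_mm`, `fov`, `scores`, `chosen_region`, `decision`)
#'   and `volumes` (the acquired subject volume per step), plus
#'   `stopped_early`/`stop_reason`.
#' @export
run_zoom <- function(truth, normative_truths, resolutions_mm = c(4, 2, 1),
                     threshold = 3, seed = 1, noise_sd0 = 0) {
  stopifnot(inherits(truth, "volume_grid"))
  if (length(normative_truths) < 2)
    stop("need >= 2 normative subjects")
  if (any(diff(resolutions_mm) >= 0))
    stop("`resolutions_mm` must be strictly decreasing")
  cur_fov <- volume_fov(truth)
  steps <- list()
  volumes <- list()
  stopped_early <- FALSE
  stop_reason <- NULL
  for (it in seq_along(resolutions_mm)) {
    res <- resolutions_mm[it]
    if ((cur_fov$hi_mm[3] - cur_fov$lo_mm[3]) / res < 3) {
      stopped_early <- TRUE
      stop_reason <- sprintf(
        "fov z-extent %.1f mm is below 3 voxels at %.1f mm resolution",
        cur_fov$hi_mm[3] - cur_fov$lo_mm[3], res)
      break
    }
    sub_vol <- acquire(truth, res, cur_fov, noise_sd0 = noise_sd0,
                       seed = child_seed(seed, paste0("acq-subject-", it)))
    snapped <- volume_fov(sub_vol)
    norm_vols <- lapply(seq_along(normative_truths), function(j)
      acquire(normative_truths[[j]], res, snapped, noise_sd0 = noise_sd0,
              seed = child_seed(seed, sprintf("acq-norm-%d-%d", it, j))))
    norm_thirds <- lapply(norm_vols, split_thirds)
    sub_thirds_fov <- lapply(split_thirds(sub_vol), volume_fov)
    norms <- lapply(1:3, function(r)
      normative_sample(vapply(norm_thirds, function(tt) scan_summary(tt[[r]]),
                              numeric(1)),
                       resolution_mm = rep(res, 3), fov = sub_thirds_fov[[r]]))
    scores <- score_thirds(sub_vol, norms)
    chosen <- pick_region(scores)
    dmax <- max(vapply(scores, function(s) s$distance, numeric(1)))
    steps[[it]] <- list(iteration = it - 1L, voxel_mm = res, fov = snapped,
                        scores = scores, chosen_region = chosen,
                        decision = stop_or_continue(dmax, threshold))
    volumes[[it]] <- sub_vol
    cur_fov <- scores[[chosen + 1L]]$fov
  }
  structure(list(steps = steps, volumes = volumes,
                 stopped_early = stopped_early, stop_reason = stop_reason),
            class = "composite_image")
}

#' @export
print.composite_image <- function(x, ...) {
  cat(sprintf("<composite_image: %d acquisition steps%s>\n", length(x$steps),
              if (x$stopped_early) " (stopped early)" else ""))
  for (s in x$steps) {
    d <- vapply(s$scores, function(z) z$distance, numeric(1))
    cat(sprintf("  step %d @ %g mm: distances (%s), chose region %d [%s]\n",
                s$iteration, s$voxel_mm,
                paste(sprintf("%.2f", d), collapse = ", "),
                s$chosen_region, s$decision))
  }
  invisible(x)
}
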