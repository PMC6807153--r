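# Robust outlier distance of a scan (or scan subdivision) from a normative
# sample -- the decision signal of the resolution-zoom loop.

#' Scalar summary of a scan
#'
#' The summary statistic the zoom loop scores: signal intensity averaged
#' across all voxels of the volume.
#'
#' @param vol a `volume_grid`.
#' @return The mean intensity (scalar).
#' @export
scan_summary <- function(vol) {
  stopifnot(inherits(vol, "volume_grid"))
  if (length(vol$data) == 0) stop("empty volume")
  mean(vol$data)
}

#' Split a volume into three equal z-thirds
#'
#' Divides the volume into three contiguous slabs along z (region 0 = lowest
#' z). When the slab count is not divisible by 3, the remainder slabs go to
#' the lowest regions, one each (so 10 slabs split 4/3/3 and 14 split
#' 5/5/4); sizes differ by at most one slab.
#'
#' @param vol a `volume_grid` with at least 3 z-slabs.
#' @return A list of three `volume_grid`s in z-order.
#' @export
split_thirds <- function(vol) {
  stopifnot(inherits(vol, "volume_grid"))
  nz <- dim(vol$data)[3]
  if (nz < 3) stop("z extent must be at least 3 voxels to split into thirds")
  base <- nz %/% 3L
  sizes <- base + (seq_len(3L) <= nz - 3L * base)
  starts <- cumsum(c(0L, sizes[-3]))
  lapply(1:3, function(r) {
    zidx <- starts[r] + seq_len(sizes[r])
    sub <- vol$data[, , zidx, drop = FALSE]
    volume_grid(sub, voxel_mm = vol$voxel_mm,
                origin_mm = vol$origin_mm + c(0, 0, starts[r] * vol$voxel_mm[3]))
  })
}

#' Normative sample of scan summaries
#'
#' Per-subject summary intensities from a reference ("normative") group,
#' computed at a fixed resolution and field of view; the provenance is
#' recorded so that subjects are only ever scored against summaries computed
#' under the same acquisition geometry.
#'
#' @param summaries numeric vector of per-subject summaries (>= 2 subjects).
#' @param resolution_mm voxel size at which the summaries were computed.
#' @param fov the `fov` over which the summaries were computed.
#' @return An object of class `normative_sample`.
#' @export
normative_sample <- function(summaries, resolution_mm, fov) {
  summaries <- as.numeric(summaries)
  if (length(summaries) < 2) stop("a normative sample needs >= 2 subjects")
  if (any(!is.finite(summaries))) stop("normative summaries must be finite")
  structure(list(summaries = summaries,
                 resolution_mm = rep_len(as.numeric(resolution_mm), 3L),
                 fov = fov),
            class = "normative_sample")
}

#' Robust outlier distance from a normative sample
#'
#' The median absolute distance between the subject's summary and each
#' normative subject's summary, scaled by the (normal-consistent) median
#' absolute deviation of the normative summaries:
#' `D(x) = median_i |x - s_i| / (constant * median_i |s_i - median(s)|)`.
#' Robust numerator and robust denominator make D a dimensionless robust
#' z-score, invariant to any common positive affine intensity transform of
#' subject and normative sample together, and comparable across
#' resolutions. `scale = "raw"` returns the unscaled median distance for
#' inspection.
#'
#' @param x the subject's scalar summary.
#' @param norm a `normative_sample`.
#' @param constant MAD consistency constant (1.4826 for normality).
#' @param scale `"mad"` (default) or `"raw"` (unscaled median distance).
#' @return A non-negative scalar distance.
#' @export
outlier_distance <- function(x, norm, constant = 1.4826, scale = c("mad", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(norm, "normative_sample"))
  if (!is.finite(x)) stop("`x` must be finite")
  s <- norm$summaries
  med_dist <- stats::median(abs(x - s))
  if (scale == "raw") return(med_dist)
  mad_s <- stats::median(abs(s - stats::median(s)))
  if (mad_s <= 0)
    stop("degenerate normative sample: MAD of summaries is zero")
  med_dist / (constant * mad_s)
}

#' Score a scan's z-thirds against per-third normative samples
#'
#' Applies [split_thirds()], [scan_summary()] and [outlier_distance()] to
#' each third; the normative samples must have been computed at the same
#' resolution and the same per-third fields of view (provenance mismatch is
#' an error).
#'
#' @param vol a `volume_grid`.
#' @param norm_per_third list of three `normative_sample`s in z-order.
#' @param ... passed to [outlier_distance()].
#' @return A list of three `subvolume_score`s (fields `region` 0-2, `fov`,
#'   `distance`) in z-order.
#' @export
score_thirds <- function(vol, norm_per_third, ...) {
  stopifnot(inherits(vol, "volume_grid"), length(norm_per_third) == 3L)
  thirds <- split_thirds(vol)
  lapply(1:3, function(r) {
    nrm <- norm_per_third[[r]]
    stopifnot(inherits(nrm, "normative_sample"))
    tb <- volume_fov(thirds[[r]])
    if (any(abs(nrm$resolution_mm - vol$voxel_mm) > 1e-6))
      stop("provenance mismatch: normative summaries were computed at a different resolution")
    if (!fov_equal(nrm$fov, tb, tol = 1e-4))
      stop("provenance mismatch: normative summaries were computed over a different fov")
    structure(list(region = r - 1L, fov = tb,
                   distance = outlier_distance(scan_summary(thirds[[r]]), nrm, ...)),
              class = "subvolume_score")
  })
}
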