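# Simulated acquisition: sample an underlying ground-truth volume at a
# requested voxel resolution and restricted field of view.

#' "Acquire" a scan of a ground-truth volume
#'
#' Simulates scanning by block-averaging: each output voxel is the mean of
#' all truth voxels whose centres fall inside its physical box (a crude
#' partial-volume model that preserves regional means exactly). The
#' simulation only ever samples down: the requested voxel size must be at
#' least the truth's. The requested field of view is snapped outward to a
#' whole number of output voxels on the output lattice anchored at the
#' truth origin (then clamped to the truth bounds); the snapped box is
#' recorded in the result's geometry and in the `fov_requested` attribute.
#' Acquiring at the truth's own resolution over its full field of view
#' returns the truth intensities unchanged.
#'
#' @param truth a `volume_grid`, the ground-truth scan.
#' @param voxel_mm requested isotropic voxel size (scalar) or length-3 mm.
#' @param fov a `fov`, the requested physical box; default: truth's full box.
#' @param noise_sd0 optional acquisition noise: if positive, i.i.d. Gaussian
#'   noise with SD `noise_sd0 / sqrt(voxel volume)` is added (SNR improves
#'   with voxel volume, mimicking the resolution/SNR trade-off). Seeded by
#'   `seed`. Default 0 (noise-free).
#' @param seed seed for acquisition noise (ignored when `noise_sd0 = 0`).
#' @return A `volume_grid` at the requested resolution covering the snapped
#'   field of view.
#' @export
acquire <- function(truth, voxel_mm, fov = volume_fov(truth),
                    noise_sd0 = 0, seed = 1) {
  stopifnot(inherits(truth, "volume_grid"), inherits(fov, "fov"))
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  tol <- 1e-9
  if (any(voxel_mm < truth$voxel_mm - tol))
    stop("cannot synthesise detail: requested voxel size is finer than the truth")
  tbox <- volume_fov(truth)
  if (!fov_contains(tbox, fov))
    stop("requested fov extends beyond the truth volume")

  # snap the fov outward onto the output lattice anchored at the truth origin
  lo <- truth$origin_mm +
    floor((fov$lo_mm - truth$origin_mm) / voxel_mm + tol) * voxel_mm
  n_out <- as.integer(ceiling((fov$hi_mm - lo) / voxel_mm - tol))
  n_out <- pmax(n_out, 1L)
  hi <- lo + n_out * voxel_mm
  over <- hi - tbox$hi_mm
  shift <- pmax(0, over)
  lo <- lo - shift
  hi <- hi - shift
  if (any(lo < tbox$lo_mm - 1e-6))
    stop("requested fov cannot be tiled by the requested voxel size inside the truth")

  dims <- dim(truth$data)
  bins <- vector("list", 3L)
  keep <- vector("list", 3L)
  for (k in 1:3) {
    centres <- truth$origin_mm[k] + (seq_len(dims[k]) - 0.5) * truth$voxel_mm[k]
    b <- floor((centres - lo[k]) / voxel_mm[k]) + 1L
    ok <- which(b >= 1L & b <= n_out[k])
    if (length(ok) == 0L) stop("empty fov: no truth voxel centres fall inside")
    keep[[k]] <- ok
    bins[[k]] <- as.integer(b[ok])
  }
  cropped <- truth$data[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]

  # aggregate axis by axis: sums then counts, mean = sums / counts
  agg_axis <- function(a, bin, m) {
    n <- dim(a)[1]
    s <- rowsum(matrix(a, n, prod(dim(a)[-1])), bin, reorder = TRUE)
    array(s, dim = c(m, dim(a)[-1]))
  }
  sums <- agg_axis(cropped, bins[[1]], n_out[1])
  sums <- aperm(agg_axis(aperm(sums, c(2, 1, 3)), bins[[2]], n_out[2]), c(2, 1, 3))
  sums <- aperm(agg_axis(aperm(sums, c(3, 2, 1)), bins[[3]], n_out[3]), c(3, 2, 1))
  cnt <- lapply(1:3, function(k) tabulate(bins[[k]], n_out[k]))
  counts <- outer(outer(cnt[[1]], cnt[[2]]), cnt[[3]])
  if (any(counts == 0))
    stop("requested voxel grid has empty cells over the truth lattice")
  out <- sums / counts
  if (noise_sd0 > 0) {
    sd_n <- noise_sd0 / sqrt(prod(voxel_mm))
    out <- out + with_seed(seed, array(stats::rnorm(length(out), 0, sd_n),
                                       dim = dim(out)))
  }
  res <- volume_grid(out, voxel_mm = voxel_mm, origin_mm = lo)
  attr(res, "fov_requested") <- fov
  attr(res, "fov_snap_mm") <- fov$lo_mm - lo
  res
}
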