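#' Volume grid: a 3D intensity lattice with physical geometry
#'
#' The unit of "a scan": a 3D array of intensities plus the voxel size,
#' the physical position of the first voxel's corner, and (derived) the
#' physical field-of-view extents. Physical coordinates are 0-based
#' millimetres; a volume occupies the half-open box
#' `[origin_mm, origin_mm + fov_mm)`.
#'
#' @param data numeric 3D array of intensities.
#' @param voxel_mm length-3 positive numeric, mm per voxel along x, y, z.
#' @param origin_mm length-3 numeric, physical position (mm) of the corner of
#'   the first voxel. Defaults to the origin.
#'
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, voxel_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  origin_mm <- rep_len(as.numeric(origin_mm), 3L)
  if (any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("`voxel_mm` must be positive and finite")
  structure(
    list(data = data, voxel_mm = voxel_mm, origin_mm = origin_mm),
    class = "volume_grid"
  )
}

#' Physical field-of-view of a volume
#'
#' @param vol a `volume_grid`.
#' @return A `fov` object: the half-open physical box `[lo_mm, hi_mm)`
#'   covered by the volume.
#' @export
volume_fov <- function(vol) {
  stopifnot(inherits(vol, "volume_grid"))
  fov(vol$origin_mm, vol$origin_mm + dim(vol$data) * vol$voxel_mm)
}

#' Physical box (field of view)
#'
#' @param lo_mm,hi_mm length-3 numeric bounds in mm; `lo_mm < hi_mm` on every
#'   axis. The box is half-open: `[lo_mm, hi_mm)`.
#' @return An object of class `fov`.
#' @export
fov <- function(lo_mm, hi_mm) {
  lo_mm <- rep_len(as.numeric(lo_mm), 3L)
  hi_mm <- rep_len(as.numeric(hi_mm), 3L)
  if (any(!is.finite(c(lo_mm, hi_mm))))
    stop("fov bounds must be finite")
  if (any(hi_mm <= lo_mm))
    stop("fov must satisfy lo < hi on every axis")
  structure(list(lo_mm = lo_mm, hi_mm = hi_mm), class = "fov")
}

#' @export
print.fov <- function(x, ...) {
  cat(sprintf("<fov [%s) x [%s) x [%s) mm>\n",
              paste(signif(c(x$lo_mm[1], x$hi_mm[1]), 6), collapse = ", "),
              paste(signif(c(x$lo_mm[2], x$hi_mm[2]), 6), collapse = ", "),
              paste(signif(c(x$lo_mm[3], x$hi_mm[3]), 6), collapse = ", ")))
  invisible(x)
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid %d x %d x %d voxels @ %s mm, origin (%s) mm>\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_mm, 4), collapse = " x "),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

fov_contains <- function(outer, inner, tol = 1e-6) {
  all(inner$lo_mm >= outer$lo_mm - tol) && all(inner$hi_mm <= outer$hi_mm + tol)
}

fov_equal <- function(a, b, tol = 1e-6) {
  all(abs(a$lo_mm - b$lo_mm) < tol) && all(abs(a$hi_mm - b$hi_mm) < tol)
}

point_in_fov <- function(p, box) {
  all(p >= box$lo_mm) && all(p < box$hi_mm)
}

#' Write / read a volume as NIfTI-1
#'
#' Voxel size is carried in the NIfTI header (`pixdim`); the physical origin
#' is carried in the sform/qform translation. Axis order is x, y, z.
#'
#' @param vol a `volume_grid`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume_nifti` returns `path` invisibly; `read_volume_nifti`
#'   returns a `volume_grid`.
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  img <- RNifti::asNifti(vol$data)
  xform <- diag(c(vol$voxel_mm, 1))
  xform[1:3, 4] <- vol$origin_mm
  img <- RNifti::`sform<-`(img, structure(xform, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  volume_grid(array(as.numeric(img), dim = dim(img)),
              voxel_mm = RNifti::pixdim(img)[1:3],
              origin_mm = xf[1:3, 4])
}
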