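# Synthetic data generators: brain-like phantoms with focal lesions, and
# multimodal cohorts with a one-factor covariance structure and an age trend.

# Separable 3D Gaussian smoothing (edge-renormalised), sigma in voxels.
gauss_smooth3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  smooth_axis <- function(a) {
    # convolve along dim 1 of a 3D array via a dense band matrix
    n <- dim(a)[1]
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1 & j <= n
      K[cbind(idx[ok], j[ok])] <- k[off + r + 1]
    }
    K <- K / rowSums(K)
    array(K %*% matrix(a, n, prod(dim(a)[-1])), dim = dim(a))
  }
  arr <- smooth_axis(arr)
  arr <- aperm(smooth_axis(aperm(arr, c(2, 1, 3))), c(2, 1, 3))
  aperm(smooth_axis(aperm(arr, c(3, 2, 1))), c(3, 2, 1))
}

#' Generate a brain-like phantom volume
#'
#' Builds a 1 mm isotropic volume containing a smooth two-shell ellipsoid
#' ("cortex" shell around a brighter "white-matter" core) on a near-zero
#' background, plus spatially correlated noise (Gaussian-smoothed white
#' noise), standing in for a T1-weighted structural scan. Between-subject
#' variability has two components mimicking scanner/session differences: a
#' global multiplicative gain on the tissue signal and a global additive
#' intensity offset. The offset makes the between-subject variance of
#' regional summaries comparable across brain-dense and background-heavy
#' regions, which keeps MAD-normalised outlier distances commensurable
#' between regions. The brain mask (outer ellipsoid) occupies 40-70% of the
#' grid and is attached as the `brain_mask` attribute.
#'
#' @param shape_mm length-3 positive numeric: physical extent of the grid in
#'   mm (1 mm voxels, so also the grid dimensions).
#' @param seed integer; the phantom is deterministic given the seed.
#' @param noise_sd SD of the correlated noise field, intensity units.
#' @param noise_fwhm_mm full width at half maximum of the noise smoothing
#'   kernel, mm.
#' @param gain_sd SD of the per-subject multiplicative intensity gain
#'   (applied to the tissue signal, not the noise).
#' @param offset_sd SD of the per-subject additive intensity offset
#'   (applied everywhere, intensity units).
#' @param tissue length-2 numeric: intensities of the outer shell and the
#'   inner core.
#' @param semi_frac semi-axes of the outer ellipsoid as a fraction of each
#'   half-extent (mask volume fraction is `pi/6 * semi_frac^3`); the default
#'   0.95 gives a brain mask filling ~45% of the grid.
#' @return A `volume_grid` at 1 mm resolution with a logical `brain_mask`
#'   attribute.
#' @export
make_phantom <- function(shape_mm, seed, noise_sd = 1, noise_fwhm_mm = 3,
                         gain_sd = 0.001, offset_sd = 2,
                         tissue = c(60, 100), semi_frac = 0.95) {
  shape_mm <- rep_len(as.numeric(shape_mm), 3L)
  if (any(!is.finite(shape_mm)) || any(shape_mm <= 0))
    stop("`shape_mm` must be positive on every axis")
  dims <- pmax(3L, as.integer(round(shape_mm)))
  centre <- dims / 2
  semi <- semi_frac * dims / 2
  ax <- lapply(1:3, function(k) ((seq_len(dims[k]) - 0.5) - centre[k]) / semi[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  r <- sqrt(r2)
  # soft shell boundaries ~1 mm wide (in normalised radius units)
  edge <- 1 / min(semi)
  w_outer <- stats::plogis((1 - r) / (0.5 * edge))
  w_inner <- stats::plogis((0.7 - r) / (0.5 * edge))
  signal <- tissue[1] * w_outer + (tissue[2] - tissue[1]) * w_inner
  with_seed(seed, {
    gain <- 1 + stats::rnorm(1, 0, gain_sd)
    offset <- stats::rnorm(1, 0, offset_sd)
    noise <- array(stats::rnorm(prod(dims)), dim = dims)
  })
  sigma_vox <- noise_fwhm_mm / (2 * sqrt(2 * log(2)))
  noise <- gauss_smooth3d(noise, sigma_vox)
  noise <- noise * (noise_sd / stats::sd(as.vector(noise)))
  vol <- volume_grid(gain * signal + offset + noise, voxel_mm = c(1, 1, 1))
  attr(vol, "brain_mask") <- r < 1
  vol
}

#' Specify a focal lesion
#'
#' A sphere in phantom physical space whose interior intensity is shifted by
#' `intensity_delta` (negative for a hypointense lesion, as in chronic
#' stroke on T1). The default radius of 13.6 mm gives a 10.6 cm^3 sphere,
#' the mean lesion volume of the stroke cohort the Scenario-1 simulation
#' emulates.
#'
#' @param center_mm length-3 numeric, lesion centre in mm (physical space).
#' @param radius_mm positive radius in mm.
#' @param intensity_delta signed intensity shift inside the sphere.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, radius_mm = 13.6, intensity_delta = -30) {
  center_mm <- rep_len(as.numeric(center_mm), 3L)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("`radius_mm` must be > 0")
  structure(list(center_mm = center_mm, radius_mm = radius_mm,
                 intensity_delta = intensity_delta),
            class = "lesion_spec")
}

#' Add a focal lesion to a phantom
#'
#' Shifts intensities inside the lesion sphere by `intensity_delta`, with a
#' soft edge: a smoothstep ramp of total width `edge_mm` centred on the
#' nominal radius, so the half-maximum surface of the intensity change sits
#' exactly at `radius_mm` and voxels beyond `radius_mm + edge_mm` are
#' untouched.
#'
#' @param vol a `volume_grid` (typically from [make_phantom()]).
#' @param lesion a `lesion_spec`.
#' @param edge_mm soft-edge width in mm (1-2 mm is realistic for partial
#'   volume at 1 mm resolution).
#' @return The lesioned `volume_grid` (attributes preserved).
#' @export
add_lesion <- function(vol, lesion, edge_mm = 1.5) {
  stopifnot(inherits(vol, "volume_grid"), inherits(lesion, "lesion_spec"))
  box <- volume_fov(vol)
  if (!point_in_fov(lesion$center_mm, box))
    stop("lesion centre lies outside the volume bounds")
  mask <- attr(vol, "brain_mask")
  if (!is.null(mask)) {
    idx <- pmin(dim(vol$data),
                pmax(1L, ceiling((lesion$center_mm - vol$origin_mm) / vol$voxel_mm)))
    if (!mask[idx[1], idx[2], idx[3]])
      warning("lesion centre is outside the phantom brain mask")
  }
  if (lesion$intensity_delta == 0) return(vol)
  dims <- dim(vol$data)
  cc <- lapply(1:3, function(k)
    vol$origin_mm[k] + (seq_len(dims[k]) - 0.5) * vol$voxel_mm[k] - lesion$center_mm[k])
  d <- sqrt(outer(outer(cc[[1]]^2, cc[[2]]^2, `+`), cc[[3]]^2, `+`))
  # smoothstep ramp on [r - e/2, r + e/2]
  t <- pmin(1, pmax(0, (lesion$radius_mm + edge_mm / 2 - d) / edge_mm))
  w <- t * t * (3 - 2 * t)
  out <- vol
  out$data <- vol$data + lesion$intensity_delta * w
  out
}

#' Specify a synthetic multimodal cohort
#'
#' Defines a cohort whose per-subject modality summaries follow a one-factor
#' model with an added linear age trend: for subject i and modality m,
#' `x[i, m] = loadings[m] * f[i] + age_slopes[m] * (age[i] - mean age) +
#' noise_sd[m] * eps[i, m]`, with `f` and `eps` standard normal and ages
#' uniform on `age_range`. This emulates a multimodal ageing cohort in which
#' the modalities share a single latent dimension of cross-subject
#' covariance.
#'
#' @param n_subjects number of subjects.
#' @param n_modalities number of modalities (>= 2; default 6).
#' @param loadings factor loadings in `[-1, 1]`, one per modality.
#' @param noise_sd positive residual SD per modality.
#' @param age_slopes linear age effect per modality (summary units / year).
#' @param age_range length-2 ages in years (default 18-88).
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, n_modalities = 6,
                        loadings = rep(0.8, n_modalities),
                        noise_sd = rep(0.5, n_modalities),
                        age_slopes = rep(0, n_modalities),
                        age_range = c(18, 88), seed = 1) {
  loadings <- rep_len(as.numeric(loadings), n_modalities)
  noise_sd <- rep_len(as.numeric(noise_sd), n_modalities)
  age_slopes <- rep_len(as.numeric(age_slopes), n_modalities)
  if (n_modalities < 2) stop("`n_modalities` must be >= 2")
  if (length(loadings) != n_modalities || length(noise_sd) != n_modalities)
    stop("`loadings`/`noise_sd` length must match `n_modalities`")
  if (any(abs(loadings) > 1)) stop("|loadings| must be <= 1")
  if (any(noise_sd <= 0)) stop("`noise_sd` must be > 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_modalities = as.integer(n_modalities),
                 loadings = loadings, noise_sd = noise_sd,
                 age_slopes = age_slopes, age_range = as.numeric(age_range),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a multimodal cohort
#'
#' Draws the cohort defined by a [cohort_spec()]; deterministic given the
#' spec's seed.
#'
#' @param spec a `cohort_spec`.
#' @return A `cohort_table`: list with `subjects` (ids), `ages` (years),
#'   `values` (subject x modality matrix) and `modalities` (names
#'   `mod_1..mod_K`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  K <- spec$n_modalities
  with_seed(spec$seed, {
    f <- stats::rnorm(n)
    ages <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    eps <- matrix(stats::rnorm(n * K), n, K)
  })
  a_c <- ages - mean(spec$age_range)
  x <- f %*% t(spec$loadings) +
    a_c %*% t(spec$age_slopes) +
    eps * rep(spec$noise_sd, each = n)
  cohort_table(subjects = sprintf("sub-%04d", seq_len(n)), ages = ages,
               values = x, modalities = paste0("mod_", seq_len(K)))
}

#' Cohort table: subject x modality summary statistics with ages
#'
#' @param subjects character subject ids.
#' @param ages numeric ages in years.
#' @param values numeric subject x modality matrix; no missing cells.
#' @param modalities character modality names (columns of `values`).
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(subjects, ages, values, modalities = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(modalities)) modalities <- paste0("mod_", seq_len(ncol(values)))
  if (length(subjects) != nrow(values) || length(ages) != nrow(values))
    stop("`subjects`, `ages` and rows of `values` must agree")
  if (anyNA(values) || anyNA(ages)) stop("cohort must have no missing cells")
  dimnames(values) <- list(subjects, modalities)
  structure(list(subjects = as.character(subjects), ages = as.numeric(ages),
                 values = values, modalities = as.character(modalities)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table: %d subjects x %d modalities, ages %.1f-%.1f>\n",
              length(x$subjects), length(x$modalities),
              min(x$ages), max(x$ages)))
  invisible(x)
}

#' Write / read a cohort as a tab-delimited table
#'
#' Header row is `subject`, `age`, then the modality names.
#'
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @return `write_cohort_tsv` returns `path` invisibly; `read_cohort_tsv`
#'   returns a `cohort_table`.
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- data.frame(subject = cohort$subjects, age = cohort$ages,
                   cohort$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("subject", "age") %in% names(df)))
    stop("cohort table must have `subject` and `age` columns")
  mods <- setdiff(names(df), c("subject", "age"))
  cohort_table(df$subject, df$age, as.matrix(df[mods]), mods)
}
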