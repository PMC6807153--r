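# Shared fixtures and independent brute-force oracles.

# Small test volume with prescribed intensities.
tiny_volume <- function(values, dims = c(2, 2, 3), voxel = 1, origin = c(0, 0, 0)) {
  volume_grid(array(values, dim = dims), voxel_mm = rep(voxel, 3),
              origin_mm = origin)
}

# Independent outlier-distance oracle: sorts and enumerates all |x - s_i|
# explicitly, with its own median.
med_sorted <- function(v) {
  v <- sort(v)
  m <- length(v)
  if (m %% 2 == 1) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
}

brute_outlier_distance <- function(x, s, constant = 1.4826) {
  num <- med_sorted(abs(x - s))
  num / (constant * med_sorted(abs(s - med_sorted(s))))
}

# Independent block-average oracle: explicit loop over truth voxel centres,
# binning each into the output voxel whose physical box contains it.
brute_block_average <- function(truth, voxel_out, lo, n_out) {
  sums <- array(0, dim = n_out)
  counts <- array(0, dim = n_out)
  dims <- dim(truth$data)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    ctr <- truth$origin_mm + (c(i, j, k) - 0.5) * truth$voxel_mm
    b <- floor((ctr - lo) / voxel_out) + 1
    if (all(b >= 1) && all(b <= n_out)) {
      sums[b[1], b[2], b[3]] <- sums[b[1], b[2], b[3]] + truth$data[i, j, k]
      counts[b[1], b[2], b[3]] <- counts[b[1], b[2], b[3]] + 1
    }
  }
  sums / counts
}

# Default Scenario-1 phantom geometry used across tests: lesion strictly
# inside the top z-third, centre inside the brain mask.
phantom_shape <- c(24, 24, 84)
lesion_centre <- c(12, 12, 70)

# Normative phantom set + the 10x-SD lesion amplitude for a given
# experiment seed (delta coupled to the observed between-subject summary
# spread at the coarse resolution).
scenario1_setup <- function(exp_seed, n_norm = 7) {
  norm <- lapply(seq_len(n_norm), function(j)
    make_phantom(phantom_shape, seed = child_seed(exp_seed, paste0("n", j))))
  summ <- sapply(norm, function(v)
    sapply(split_thirds(acquire(v, 4)), scan_summary))
  list(norm = norm, delta = 10 * max(apply(summ, 1, stats::sd)))
}

# Cohort with a planted step: age jumps at x = step on modality 1 only.
step_cohort <- function(n, step = 0.3, seed = 1, noise_sd = 2) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * 3), n, 3,
              dimnames = list(NULL, paste0("mod_", 1:3)))
  age <- ifelse(x[, 1] < step, 30, 60) + stats::rnorm(n, 0, noise_sd)
  cohort_table(sprintf("s%04d", seq_len(n)), age, x)
}
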