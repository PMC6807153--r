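test_that("phantom generation is deterministic, seed-sensitive and brain-like", {
  v1 <- make_phantom(c(24, 24, 48), seed = 1)
  v2 <- make_phantom(c(24, 24, 48), seed = 1)
  v3 <- make_phantom(c(24, 24, 48), seed = 2)
  expect_identical(v1$data, v2$data)
  expect_false(any(v1$data == v3$data))
  frac <- mean(attr(v1, "brain_mask"))
  expect_gt(frac, 0.40)
  expect_lt(frac, 0.70)
  expect_identical(dim(v1$data), c(24L, 24L, 48L))
  expect_equal(v1$voxel_mm, c(1, 1, 1))
  expect_error(make_phantom(c(-10, 24, 24), seed = 1), "positive")
})

test_that("phantom background is near zero away from the brain", {
  # suppress subject-level variability and noise to isolate the construction
  v <- make_phantom(c(24, 24, 48), seed = 1, noise_sd = 1e-8, gain_sd = 0,
                    offset_sd = 0)
  expect_lt(abs(v$data[1, 1, 1]), 1e-3)
  # with default noise the corner is still background-dominated
  vn <- make_phantom(c(24, 24, 48), seed = 1, gain_sd = 0, offset_sd = 0)
  expect_lt(abs(vn$data[1, 1, 1]), 3 * 1)
})

test_that("lesions shift the sphere interior by delta and nothing else", {
  v <- make_phantom(phantom_shape, seed = 3)
  les <- lesion_spec(lesion_centre, radius_mm = 13.6, intensity_delta = -20)

  expect_identical(add_lesion(v, lesion_spec(lesion_centre, 13.6, 0))$data,
                   v$data)
  vl <- add_lesion(v, les)

  # brute-force voxel loop over the sphere region and a far region
  dims <- dim(v$data)
  in_sphere <- far <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    dz2 <- (k - 0.5 - lesion_centre[3])^2
    for (j in seq_len(dims[2])) {
      dy2 <- (j - 0.5 - lesion_centre[2])^2
      for (i in seq_len(dims[1])) {
        d <- sqrt((i - 0.5 - lesion_centre[1])^2 + dy2 + dz2)
        if (d <= 13.6) in_sphere[i, j, k] <- TRUE
        if (d > 13.6 + 1.5) far[i, j, k] <- TRUE
      }
    }
  }
  shift <- mean(vl$data[in_sphere]) - mean(v$data[in_sphere])
  expect_equal(shift, -20, tolerance = 0.05)
  expect_identical(vl$data[far], v$data[far])

  # half-maximum voxel count reproduces the nominal sphere volume
  n_changed <- sum(abs(vl$data - v$data) > 10)
  expect_equal(n_changed, 4 / 3 * pi * 13.6^3, tolerance = 0.15)

  expect_error(add_lesion(v, lesion_spec(c(500, 0, 0), 10, -5)), "outside")
  expect_error(lesion_spec(c(0, 0, 0), radius_mm = -1), "radius")
})

test_that("simulated cohorts have the prescribed factor structure", {
  # independence when loadings and age slopes vanish
  co0 <- simulate_cohort(cohort_spec(800, 4, loadings = rep(0, 4),
                                     noise_sd = rep(1, 4), seed = 5))
  cm <- stats::cor(co0$values)
  expect_lt(max(abs(cm[upper.tri(cm)])), 3 / sqrt(800))

  # closed-form factor-model correlation: rho = l^2 / (l^2 + sd^2)
  co <- simulate_cohort(cohort_spec(2000, 2, loadings = c(0.9, 0.9),
                                    noise_sd = c(0.1, 0.1), seed = 6))
  rho <- 0.9^2 / (0.9^2 + 0.1^2)
  expect_equal(stats::cor(co$values)[1, 2], rho, tolerance = 0.02)

  # full correlation matrix matches the normalised lambda lambda^T + diag
  l <- c(0.8, 0.6, -0.7, 0.5)
  sdn <- c(0.4, 0.5, 0.3, 0.6)
  co2 <- simulate_cohort(cohort_spec(2500, 4, loadings = l, noise_sd = sdn,
                                     seed = 7))
  sig <- outer(l, l) + diag(sdn^2)
  expected <- sig / sqrt(outer(diag(sig), diag(sig)))
  expect_lt(max(abs(stats::cor(co2$values) - expected)), 0.05)

  expect_identical(simulate_cohort(cohort_spec(50, 3, seed = 9))$values,
                   simulate_cohort(cohort_spec(50, 3, seed = 9))$values)
  expect_error(cohort_spec(10, 3, loadings = c(2, 0, 0)), "loadings")
  expect_error(cohort_spec(10, 3, noise_sd = c(0, 1, 1)), "noise_sd")
  expect_error(cohort_spec(10, 1), "n_modalities")
})

test_that("cohorts round-trip through the tab-delimited format", {
  co <- simulate_cohort(cohort_spec(20, 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(co, path)
  back <- read_cohort_tsv(path)
  expect_equal(back$values, co$values, tolerance = 1e-12)
  expect_equal(back$ages, co$ages, tolerance = 1e-12)
  expect_identical(back$modalities, co$modalities)
})

test_that("phantoms round-trip through NIfTI with geometry intact", {
  v <- make_phantom(c(16, 16, 24), seed = 4)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, path)
  back <- read_volume_nifti(path)
  expect_equal(back$data, unclass(v$data), tolerance = 1e-6)
  expect_equal(back$voxel_mm, v$voxel_mm)
  expect_equal(back$origin_mm, v$origin_mm, tolerance = 1e-6)
})
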