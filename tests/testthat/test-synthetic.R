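test_that("the generator is byte-identical for the same seed", {
  p <- synth_params(n_subjects = 2, n_voxels = 100, seed = 77)
  v1 <- generate_voxels(p)
  v2 <- generate_voxels(p)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  v3 <- generate_voxels(synth_params(n_subjects = 2, n_voxels = 100, seed = 78))
  expect_false(identical(v1$eccentricity, v3$eccentricity))
})

test_that("noiseless data invert through the pipeline", {
  p <- synth_params(n_subjects = 2, n_voxels = 3000, noise_sd_amp = 0,
                    seed = 19)
  vox <- voxel_sensitivities(generate_voxels(p))
  truth <- attr(generate_voxels(p), "truth")$per_voxel
  # per-voxel attributes equal their generating expectations exactly
  expect_equal(vox$cue_sensitivity, truth$expected_cue_sensitivity,
               tolerance = 1e-10)
  ok <- !is.na(vox$contrast_sensitivity)
  expect_equal(vox$contrast_sensitivity[ok],
               truth$expected_contrast_sensitivity[ok], tolerance = 1e-10)
  expect_equal(vox$amplitude, truth$expected_amplitude, tolerance = 1e-10)
  # fitted profile widths recover the generating SDs up to binning bias
  fc <- fit_spatial_gaussian(bin_profile(vox, "contrast_sensitivity"), "single")
  fq <- fit_spatial_gaussian(bin_profile(vox, "cue_sensitivity"), "single")
  expect_equal(fc$sigma, 3.44, tolerance = 5e-3)
  expect_equal(fq$sigma, 4.92, tolerance = 5e-3)
})

test_that("the fitted width ratio is near 1.4 across replicate experiments", {
  ok <- 0
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    vox <- voxel_sensitivities(generate_voxels(synth_params(seed = s)))
    r <- fit_spatial_gaussian(bin_profile(vox, "cue_sensitivity"),
                              "single")$sigma /
      fit_spatial_gaussian(bin_profile(vox, "contrast_sensitivity"),
                           "single")$sigma
    ok <- ok + (abs(r - 1.4) / 1.4 < 0.1)
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("voxel tables round-trip through the plain-text writers", {
  skip_if_not_installed("jsonlite")
  vox <- generate_voxels(synth_params(n_subjects = 2, n_voxels = 40, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_voxels(vox, dir)
  expect_true(file.exists(paths[["truth"]]))
  back <- read_voxels(paths[["voxels"]])
  expect_identical(names(back), names(vox))
  for (nm in names(vox)) {
    if (is.numeric(vox[[nm]])) {
      expect_equal(back[[nm]], vox[[nm]], tolerance = 1e-12)
    } else {
      expect_identical(as.character(back[[nm]]), as.character(vox[[nm]]))
    }
  }
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$params$sigma_cue, 4.92)
  expect_identical(nrow(truth$per_voxel), 80L)
})

test_that("coherence separates the stimulus band from the periphery", {
  vox <- generate_voxels(synth_params(n_subjects = 1, n_voxels = 2000,
                                      seed = 31))
  inside <- vox$coherence[abs(vox$eccentricity) <= 2]
  outside <- vox$coherence[abs(vox$eccentricity) >= 5]
  expect_gt(mean(inside > 0.5), 0.95)
  expect_gt(mean(outside < 0.5), 0.95)
  expect_true(all(vox$coherence >= 0 & vox$coherence <= 1))
})

test_that("the negative surround depresses amplitudes beyond the band", {
  p <- synth_params(n_subjects = 1, n_voxels = 2000, noise_sd_amp = 0,
                    surround_amp = 0.3, seed = 12)
  vox <- voxel_sensitivities(generate_voxels(p))
  # peripheral side away from the foveal component
  far <- vox$eccentricity > 7
  expect_lt(mean(vox$amplitude[far]), 0)
})

test_that("synthetic time series support coherence and amplitude recovery", {
  onsets <- data.frame(condition = "a", onset = c(20, 80, 140))
  gen <- generate_time_series(onsets, n_volumes = 210,
                              amplitudes = c(a = 0),
                              localizer_amplitude = 1, localizer_cycles = 10)
  expect_equal(compute_coherence(gen$time_series, 10), 1, tolerance = 1e-12)
  gen2 <- generate_time_series(onsets, n_volumes = 210,
                               amplitudes = c(a = 1.4))
  est <- estimate_amplitudes(gen2$time_series, onsets, n_lags = 20)
  expect_equal(est$amplitude, 1.4, tolerance = 1e-4)
})
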