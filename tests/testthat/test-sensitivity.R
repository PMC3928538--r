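make_voxel_row <- function(amps_cued, amps_uncued, fit_r2 = 0.9, ecc = 0,
                           coh = 0.8) {
  tibble::tibble(
    subject = "s01", voxel = 1L, eccentricity = ecc, coherence = coh,
    fit_r2 = fit_r2,
    amp_c12.5_cued = amps_cued[1], amp_c25_cued = amps_cued[2],
    amp_c50_cued = amps_cued[3],
    amp_c12.5_uncued = amps_uncued[1], amp_c25_uncued = amps_uncued[2],
    amp_c50_uncued = amps_uncued[3]
  )
}

test_that("contrast-sensitivity recovers an exactly linear slope", {
  s <- 0.04
  amps <- 0.2 + s * c(12.5, 25, 50)
  v <- make_voxel_row(amps, amps)
  expect_equal(contrast_sensitivity(v), s, tolerance = 1e-12)
  expect_equal(contrast_sensitivity(make_voxel_row(c(1, 1, 1), c(1, 1, 1))), 0)
})

test_that("contrast-sensitivity matches the closed-form least-squares oracle", {
  v <- make_voxel_row(c(0.5, 1.0, 1.5), c(0.5, 1.0, 1.5))
  x <- c(12.5, 25, 50); y <- c(0.5, 1.0, 1.5)
  oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(contrast_sensitivity(v), oracle, tolerance = 1e-12)
  # and agrees with lm()
  expect_equal(oracle, unname(coef(lm(y ~ x))[2]), tolerance = 1e-12)
})

test_that("low amplitude-fit quality withholds contrast-sensitivity", {
  v <- dplyr::bind_rows(
    make_voxel_row(c(0.5, 1, 1.5), c(0.5, 1, 1.5), fit_r2 = 0.9),
    make_voxel_row(c(0.5, 1, 1.5), c(0.5, 1, 1.5), fit_r2 = 0.6)
  )
  out <- voxel_sensitivities(v)
  expect_false(is.na(out$contrast_sensitivity[1]))
  expect_true(is.na(out$contrast_sensitivity[2]))
  expect_identical(attr(out, "excluded"), 1L)
  # cue-sensitivity is unaffected by the threshold
  expect_false(anyNA(out$cue_sensitivity))
})

test_that("cue-sensitivity is the mean cued-minus-uncued difference", {
  v <- make_voxel_row(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cue_sensitivity(v), 0)
  v2 <- make_voxel_row(c(1.2, 2.2, 3.2), c(1, 2, 3))
  expect_equal(cue_sensitivity(v2), 0.2, tolerance = 1e-12)
  v3 <- make_voxel_row(c(0.3, 1.1, 0.8), c(0.5, 0.2, 0.9))
  expect_equal(cue_sensitivity(v3),
               mean(c(0.3, 1.1, 0.8)) - mean(c(0.5, 0.2, 0.9)),
               tolerance = 1e-12)
  expect_error(cue_sensitivity(v3[, -6]), "lacks columns")
})

test_that("grating center is the mean eccentricity of coherent voxels", {
  v <- tibble::tibble(eccentricity = c(5, 5, 5), coherence = c(0.9, 0.8, 0.7))
  expect_equal(locate_grating_center(v), 5)
  v2 <- tibble::tibble(eccentricity = c(4, 6, 10, 20),
                       coherence = c(0.9, 0.8, 0.1, 0.2))
  expect_equal(locate_grating_center(v2), 5)
  set.seed(3)
  v3 <- tibble::tibble(eccentricity = runif(50, 0, 12),
                       coherence = runif(50))
  oracle <- mean(v3$eccentricity[v3$coherence > 0.5])
  expect_equal(locate_grating_center(v3), oracle, tolerance = 1e-12)
  expect_error(locate_grating_center(v3, threshold = 2), "No voxel")
})
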