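test_that("profiles have 17 bins and honest counts", {
  set.seed(21)
  v <- tibble::tibble(eccentricity = runif(400, -8.5, 8.5),
                      val = rnorm(400))
  prof <- bin_profile(v, "val")
  expect_identical(nrow(prof), 17L)
  expect_identical(sum(prof$count), 400L)
  # histogram oracle for the counts
  oracle <- as.integer(table(cut(v$eccentricity, seq(-8.5, 8.5, by = 1),
                                 right = FALSE)))
  expect_identical(prof$count, oracle)
})

test_that("voxels in a single bin and constant attributes behave", {
  v <- tibble::tibble(eccentricity = rep(0.2, 5), val = 1:5)
  prof <- bin_profile(v, "val")
  expect_identical(sum(prof$count > 0), 1L)
  expect_equal(prof$mean[prof$count > 0], 3)
  v2 <- tibble::tibble(eccentricity = seq(-8, 8, length.out = 30),
                       val = rep(2.5, 30))
  prof2 <- bin_profile(v2, "val")
  expect_equal(unique(prof2$mean[!is.na(prof2$mean)]), 2.5)
})

test_that("out-of-range voxels are dropped and centers respected", {
  v <- tibble::tibble(eccentricity = c(0, 20, -20, 3), val = c(1, 9, 9, 1))
  prof <- bin_profile(v, "val")
  expect_identical(sum(prof$count), 2L)
  # center shifts the relative frame
  prof_c <- bin_profile(v, "val", center = 20)
  expect_identical(sum(prof_c$count), 1L)
  expect_error(bin_profile(v[v$eccentricity > 30, ], "val"), "No voxels")
})

test_that("subject-wise binning averages subjects with equal weight", {
  v <- tibble::tibble(
    subject = rep(c("a", "b"), c(3, 1)),
    eccentricity = c(0.1, 0.2, 0.3, 0.1),
    val = c(1, 1, 1, 5)
  )
  prof <- bin_profile(v, "val")
  # equal subject weighting: (1 + 5) / 2, not the voxel-pooled mean 2
  expect_equal(prof$mean[prof$count > 0], 3)
})

test_that("a single Gaussian profile is recovered exactly from clean samples", {
  centers <- seq(-8, 8, by = 1)
  prof <- tibble::tibble(bin_center = centers,
                         mean = 0.9 * exp(-centers^2 / (2 * 3.44^2)))
  fit <- fit_spatial_gaussian(prof, "single")
  expect_equal(fit$sigma, 3.44, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.9, tolerance = 1e-6)
  expect_identical(fit$mean, 0)
  expect_identical(fit$offset, 0)
  expect_gt(fit$r2, 1 - 1e-10)
})

test_that("a sum of two Gaussians is recovered from clean samples", {
  centers <- seq(-8, 8, by = 1)
  y <- 0.8 * exp(-(centers + 6)^2 / (2 * 2.03^2)) +
    1.2 * exp(-centers^2 / (2 * 2.17^2)) + 0.05
  fit <- fit_spatial_gaussian(tibble::tibble(bin_center = centers, mean = y),
                              "sum_of_two")
  expect_equal(fit$mean[1], -6, tolerance = 1e-4)
  expect_equal(fit$sigma[1], 2.03, tolerance = 1e-4)
  expect_equal(fit$sigma[2], 2.17, tolerance = 1e-4)
  expect_equal(fit$amplitude, c(0.8, 1.2), tolerance = 1e-4)
  expect_equal(fit$offset, 0.05, tolerance = 1e-4)
  expect_identical(fit$mean[2], 0)
  # the foveal mean is constrained below -2 degrees
  expect_lte(fit$mean[1], -2)
})

test_that("flat profiles fit with near-zero amplitude and poor r2", {
  centers <- seq(-8, 8, by = 1)
  set.seed(9)
  prof <- tibble::tibble(bin_center = centers,
                         mean = rnorm(length(centers), 0, 1e-3))
  fit <- fit_spatial_gaussian(prof, "single")
  expect_lt(abs(fit$amplitude), 0.01)
  expect_lt(fit$r2, 0.9)
})

test_that("insufficient bins are rejected", {
  prof <- tibble::tibble(bin_center = -2:2, mean = exp(-(-2:2)^2 / 8))
  expect_error(fit_spatial_gaussian(prof, "single"), "at least 6")
  prof2 <- tibble::tibble(bin_center = -3:3, mean = exp(-(-3:3)^2 / 8))
  expect_error(fit_spatial_gaussian(prof2, "sum_of_two"), "at least 8")
})
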