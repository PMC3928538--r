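test_that("zero stimulus with zero baseline gives zero response", {
  cfg <- small_config(baseline_mod = 0)
  R <- model_response(cfg, stimulus_spec(contrast = 0), attention_spec("none"))
  expect_true(all(unclass(R) == 0))
})

test_that("attention mode none reproduces the unattended response bitwise", {
  cfg <- small_config()
  stim <- stimulus_spec(contrast = 40)
  R1 <- model_response(cfg, stim, attention_spec("none"))
  R2 <- model_response(cfg, stim, attention_spec("none"))
  expect_identical(unclass(R1), unclass(R2))
  pair <- contrast_response(cfg, stim, attention_spec("none"),
                            contrasts = c(0, 5, 50))
  expect_identical(pair$r_attended, pair$r_unattended)
})

test_that("responses are nonnegative and nondecreasing in contrast", {
  cfg <- small_config()
  ladder <- contrast_ladder(n = 8)
  prev <- NULL
  for (cc in ladder) {
    R <- unclass(model_response(cfg, stimulus_spec(contrast = cc),
                                attention_spec("spatial"),
                                stimulus_spatial_sd = 2))
    expect_true(all(R >= 0))
    if (!is.null(prev)) expect_true(all(R - prev >= -1e-12))
    prev <- R
  }
})

test_that("responses saturate: doubling contrast less than doubles response", {
  cfg <- small_config(sigma = 0.5)
  r1 <- max(unclass(model_response(cfg, stimulus_spec(contrast = 50),
                                   attention_spec("none"))))
  r2 <- max(unclass(model_response(cfg, stimulus_spec(contrast = 100),
                                   attention_spec("none"))))
  expect_lt(r2 / r1, 2)
  # while the drive itself is exactly linear
  e1 <- max(unclass(stimulus_drive(cfg, stimulus_spec(contrast = 50))))
  e2 <- max(unclass(stimulus_drive(cfg, stimulus_spec(contrast = 100))))
  expect_equal(e2 / e1, 2, tolerance = 1e-12)
})

test_that("for huge sigma the response approaches modulated drive over sigma", {
  cfg <- small_config(baseline_mod = 0)
  stim <- stimulus_spec(contrast = 80)
  E <- stimulus_drive(cfg, stim)
  S <- suppressive_drive(E, cfg)
  big <- 1e6 * max(unclass(S))
  cfg_big <- small_config(sigma = big, baseline_mod = 0)
  R <- unclass(model_response(cfg_big, stim, attention_spec("none")))
  lin <- unclass(E) / big
  keep <- lin > 0
  expect_lt(max(abs(R[keep] - lin[keep]) / lin[keep]), 1e-3)
})

test_that("the spiking threshold subtracts before rectification", {
  cfg <- small_config(spike_threshold = 0.05)
  cfg0 <- small_config(spike_threshold = 0)
  stim <- stimulus_spec(contrast = 30)
  R <- unclass(model_response(cfg, stim, attention_spec("none")))
  R0 <- unclass(model_response(cfg0, stim, attention_spec("none")))
  expect_equal(R, pmax(R0 - 0.05, 0), tolerance = 1e-12)
})

test_that("single-neuron scope errors for off-grid requests", {
  cfg <- small_config()
  expect_error(
    contrast_response(cfg, stimulus_spec(), attention_spec("none"),
                      contrasts = c(0, 50, 100), scope = "single_neuron",
                      x = 12, theta = 0),
    "off the simulated grid"
  )
})

test_that("contrast-response CSV round-trips", {
  cfg <- small_config()
  pair <- contrast_response(cfg, stimulus_spec(), attention_spec("spatial"),
                            contrasts = c(0, 1, 10, 50, 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contrast_response(pair, path)
  back <- read_contrast_response(path)
  expect_equal(back$r_attended, pair$r_attended, tolerance = 1e-10)
  expect_equal(back$r_unattended, pair$r_unattended, tolerance = 1e-10)
  expect_identical(names(back)[1:4],
                   c("contrast", "r_unattended", "r_attended", "scope"))
})
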