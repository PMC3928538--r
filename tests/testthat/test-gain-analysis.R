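test_that("the Naka-Rushton equation honors its landmarks", {
  expect_equal(naka_rushton(20, r_max = 2, c50 = 20, n = 3, r_offset = 0.5),
               2 / 2 + 0.5)
  expect_equal(naka_rushton(0, r_max = 2, c50 = 20, n = 3, r_offset = 0.5), 0.5)
  # hand-computed: 40^2 / (40^2 + 20^2) = 1600/2000
  expect_equal(naka_rushton(40, r_max = 1, c50 = 20, n = 2), 0.8)
  expect_error(naka_rushton(-1, 1, 20, 2), "nonnegative")
  expect_error(naka_rushton(10, 1, 0, 2), "c50")
})

test_that("each generating model is refit with variance accounted ~ 1", {
  cases <- list(
    list(free = "r_offset", expect_best = "additive-offset"),
    list(free = "r_max", expect_best = "response-gain"),
    list(free = "c50", expect_best = "contrast-gain")
  )
  for (cs in cases) {
    pair <- make_nr_pair(free = cs$free)
    fit <- fit_gain_model(pair, cs$free)
    expect_gt(fit$var_accounted, 1 - 1e-6)
    cl <- classify_attention_effect(pair)
    expect_identical(cl$best, cs$expect_best)
    expect_true(all(cl$var_accounted <= 1))
  }
})

test_that("a model generating the data beats the alternatives", {
  pair <- make_nr_pair(free = "r_max", attended_value = 1.5)
  cl <- classify_attention_effect(pair)
  expect_gt(cl$fits[["response-gain"]]$var_accounted, 1 - 1e-6)
  expect_lt(cl$fits[["additive-offset"]]$var_accounted,
            cl$fits[["response-gain"]]$var_accounted)
})

test_that("an exact vertical shift is classified additive-offset with va 1", {
  pair <- make_nr_pair(free = "r_offset", attended_value = 0.25)
  expect_equal(pair$r_attended - pair$r_unattended,
               rep(0.25, nrow(pair)))
  cl <- classify_attention_effect(pair)
  expect_identical(cl$best, "additive-offset")
  expect_equal(cl$fits[["additive-offset"]]$var_accounted, 1,
               tolerance = 1e-6)
})

test_that("identical attended and unattended curves raise a degenerate error", {
  cc <- contrast_ladder()
  r <- naka_rushton(cc, 1, 20, 2)
  pair <- tibble::tibble(contrast = cc, r_unattended = r, r_attended = r)
  expect_error(fit_gain_model(pair, "r_offset"), "degenerate")
  expect_error(classify_attention_effect(pair), "degenerate")
})

test_that("fits are deterministic and multistart-stable on noiseless input", {
  pair <- make_nr_pair(free = "c50")
  f1 <- fit_gain_model(pair, "c50")
  f2 <- fit_gain_model(pair, "c50")
  expect_identical(f1$rss, f2$rss)
  expect_identical(f1$shared, f2$shared)
  # and the multistart optimum reaches the nested truth
  expect_lt(f1$rss, 1e-10)
})

test_that("the classifier recovers the generating model under noise", {
  set.seed(42)
  frees <- c("r_offset", "c50", "r_max")
  n_per <- 20
  hits <- 0
  for (free in frees) {
    for (i in seq_len(n_per)) {
      r_max <- runif(1, 0.5, 2)
      pair <- make_nr_pair(r_max = r_max, c50 = runif(1, 5, 40),
                           n = runif(1, 1, 3), r_offset = runif(1, 0, 0.2),
                           free = free, noise_sd = 0.02 * r_max)
      cl <- classify_attention_effect(pair)
      hits <- hits + (cl$best == unname(c(
        r_offset = "additive-offset", c50 = "contrast-gain",
        r_max = "response-gain")[free]))
    }
  }
  expect_gte(hits / (3 * n_per), 0.85)
})

test_that("tidy and glance expose the fits as tibbles", {
  pair <- make_nr_pair(free = "r_offset")
  cl <- classify_attention_effect(pair)
  td <- tidy(cl)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 3L)
  expect_true(all(c("model", "var_accounted", "best") %in% names(td)))
  gl <- glance(cl)
  expect_identical(gl$best, "additive-offset")
  expect_gte(gl$margin, 0)
})
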