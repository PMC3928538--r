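#' Naka-Rushton contrast-response function
#'
#' \deqn{R(c) = R_{max} \frac{c^n}{c^n + C_{50}^n} + R_{offset}}
#'
#' @param contrast Contrast(s) in percent, >= 0.
#' @param r_max Maximum contrast-dependent response.
#' @param c50 Contrast at which the contrast-dependent response reaches half
#'   its maximum (percent, > 0).
#' @param n Exponent controlling the steepness.
#' @param r_offset Response at zero contrast.
#' @return Numeric response(s).
#' @export
#' @examples
#' naka_rushton(40, r_max = 1, c50 = 20, n = 2)  # 0.8
naka_rushton <- function(contrast, r_max, c50, n, r_offset = 0) {
  if (any(contrast < 0)) stop("`contrast` must be nonnegative.", call. = FALSE)
  if (c50 <= 0) stop("`c50` must be positive.", call. = FALSE)
  cn <- contrast^n
  r_max * cn / (cn + c50^n) + r_offset
}

# parameter order used internally: r_max, c50, n, r_offset, attended value
#' @noRd
gain_model_labels <- c(
  r_offset = "additive-offset",
  c50 = "contrast-gain",
  r_max = "response-gain"
)

#' Fit one attention-effect model to a contrast-response pair
#'
#' Jointly fits the Naka-Rushton equation to the attended and unattended
#' curves by least squares on the raw responses of both curves, with all
#' parameters shared except one, which takes a separate value in the
#' attended condition: `r_max` for the response-gain model, `c50` for the
#' contrast-gain model, `r_offset` for the additive-offset model.
#'
#' Goodness of the attention effect is summarized as variance accounted
#' for: one minus the residual variance of the attended-minus-unattended
#' difference divided by the actual variance of that difference, both taken
#' about zero (the difference has a meaningful zero, so a pure vertical
#' shift is fully credited to the additive-offset model). It may be
#' negative and is reported unclamped.
#'
#' Optimization is bounded quasi-Newton least squares from 10 deterministic
#' multistart initializations (bounds: `r_max` in `[0, 10 max(r)]`, `c50`
#' in `[min positive contrast/10, 10 max contrast]`, `n` in `[0.5, 6]`,
#' `r_offset` in `[-max(r), max(r)]`).
#'
#' @param pair A `contrast_response_pair` (or tibble with columns
#'   `contrast`, `r_unattended`, `r_attended`), >= 5 contrast levels.
#' @param free_param One of `"r_max"`, `"c50"`, `"r_offset"`.
#' @param n_starts Number of multistart initializations (default 10).
#' @return An object of class `gain_fit`: list with elements `free_param`,
#'   `label`, `shared` (named unattended-curve parameters), `attended_value`,
#'   `var_accounted`, `rss`.
#' @export
fit_gain_model <- function(pair, free_param = c("r_offset", "c50", "r_max"),
                           n_starts = 10) {
  free_param <- match.arg(free_param)
  dat <- check_pair(pair)
  diff_obs <- dat$r_attended - dat$r_unattended
  if (mean(diff_obs^2) == 0) {
    stop("Attended and unattended responses are identical; ",
         "the attention effect is degenerate and cannot be classified.",
         call. = FALSE)
  }
  cc <- dat$contrast
  r_all <- c(dat$r_unattended, dat$r_attended)
  rmax_hi <- 10 * max(r_all, 1e-12)
  cpos <- cc[cc > 0]
  c50_lo <- min(cpos) / 10
  c50_hi <- 10 * max(cc)
  off_hi <- max(abs(r_all), 1e-12)

  lower <- c(r_max = 0, c50 = c50_lo, n = 0.5, r_offset = -off_hi)
  upper <- c(r_max = rmax_hi, c50 = c50_hi, n = 6, r_offset = off_hi)
  lower <- c(lower, free = lower[[free_param]])
  upper <- c(upper, free = upper[[free_param]])

  predict_both <- function(p) {
    ru <- naka_rushton(cc, p[1], p[2], p[3], p[4])
    pa <- p[1:4]
    pa[match(free_param, c("r_max", "c50", "n", "r_offset"))] <- p[5]
    ra <- naka_rushton(cc, pa[1], pa[2], pa[3], pa[4])
    list(ru = ru, ra = ra)
  }
  obj <- function(p) {
    pr <- predict_both(p)
    sum((pr$ru - dat$r_unattended)^2) + sum((pr$ra - dat$r_attended)^2)
  }

  starts <- gain_fit_starts(dat, free_param, n_starts, lower, upper)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Gain-model fit failed to converge.", call. = FALSE)

  p <- best$par
  pr <- predict_both(p)
  diff_model <- pr$ra - pr$ru
  # variance about zero (mean square): the attention-effect difference has a
  # meaningful zero, and a pure vertical shift must be fully creditable to
  # the additive-offset model
  var_accounted <- 1 - mean((diff_obs - diff_model)^2) / mean(diff_obs^2)
  structure(
    list(
      free_param = free_param,
      label = gain_model_labels[[free_param]],
      shared = c(r_max = unname(p[1]), c50 = unname(p[2]),
                 n = unname(p[3]), r_offset = unname(p[4])),
      attended_value = unname(p[5]),
      var_accounted = var_accounted,
      rss = best$value
    ),
    class = "gain_fit"
  )
}

#' @noRd
check_pair <- function(pair) {
  need <- c("contrast", "r_unattended", "r_attended")
  if (!is.data.frame(pair) || !all(need %in% names(pair))) {
    stop("`pair` must have columns contrast, r_unattended, r_attended.",
         call. = FALSE)
  }
  dat <- as.data.frame(pair)[, need]
  if (nrow(dat) < 5L) stop("At least 5 contrast levels are required.", call. = FALSE)
  if (!all(is.finite(unlist(dat)))) stop("Responses must be finite.", call. = FALSE)
  dat
}

# deterministic multistart grid: a heuristic center scaled by fixed factors
#' @noRd
gain_fit_starts <- function(dat, free_param, n_starts, lower, upper) {
  cc <- dat$contrast
  cpos <- cc[cc > 0]
  r0 <- min(dat$r_unattended)
  rmax0 <- max(max(dat$r_unattended) - r0, 1e-9)
  # contrast nearest half rise of the unattended curve
  half <- r0 + rmax0 / 2
  c50_0 <- cpos[which.min(abs(dat$r_unattended[cc > 0] - half))]
  base <- c(rmax0, c50_0, 2, r0)
  free0 <- switch(free_param,
                  r_max = max(max(dat$r_attended) - min(dat$r_attended), 1e-9),
                  c50 = c50_0,
                  r_offset = min(dat$r_attended))
  center <- c(base, free0)
  scales <- cbind(
    r_max = c(1, 1, 0.5, 2, 1, 1, 0.5, 2, 1, 1.5),
    c50 = c(1, 0.3, 1, 1, 3, 0.3, 3, 0.3, 1, 1),
    n = c(1, 1, 1, 1, 1, 0.5, 0.75, 1.5, 2.5, 1),
    r_offset = rep(1, 10),
    free = c(1, 1, 0.5, 2, 1, 0.5, 1, 1, 1, 0.75)
  )
  scales <- scales[seq_len(min(n_starts, nrow(scales))), , drop = FALSE]
  starts <- sweep(scales, 2, center, "*")
  # offsets can be zero; nudge alternate starts additively instead
  starts[, 4] <- center[4] + (seq_len(nrow(starts)) - 1) / nrow(starts) *
    0.1 * diff(range(dat$r_unattended))
  if (free_param == "r_offset") {
    starts[, 5] <- center[5] + (seq_len(nrow(starts)) %% 3 - 1) *
      0.1 * max(abs(dat$r_attended))
  }
  starts <- pmin(pmax(starts, matrix(lower, nrow(starts), 5, byrow = TRUE)),
                 matrix(upper, nrow(starts), 5, byrow = TRUE))
  starts
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf("<gain_fit %s> var accounted %.4f, rss %.3g\n", x$label,
              x$var_accounted, x$rss))
  cat(sprintf("  shared: r_max %.4g, c50 %.4g, n %.3g, r_offset %.4g; attended %s = %.4g\n",
              x$shared[["r_max"]], x$shared[["c50"]], x$shared[["n"]],
              x$shared[["r_offset"]], x$free_param, x$attended_value))
  invisible(x)
}

#' Classify an attention effect on contrast-response
#'
#' Fits all three one-free-parameter attention-effect models
#' (contrast-gain, response-gain, additive-offset) to an
#' attended/unattended contrast-response pair and labels the effect by the
#' model with the highest variance accounted for. Ties within 1e-9 are
#' broken by the fixed precedence additive-offset > contrast-gain >
#' response-gain.
#'
#' @inheritParams fit_gain_model
#' @return An object of class `gain_classification`: list with `fits` (the
#'   three `gain_fit`s, named by label), `best` (winning label), `margin`
#'   (best minus runner-up variance accounted for).
#' @export
#' @examples
#' cc <- contrast_ladder()
#' pair <- tibble::tibble(contrast = cc,
#'                        r_unattended = naka_rushton(cc, 1, 20, 2),
#'                        r_attended = naka_rushton(cc, 1, 20, 2) + 0.1)
#' classify_attention_effect(pair)$best
classify_attention_effect <- function(pair, n_starts = 10) {
  fits <- purrr::map(c("r_offset", "c50", "r_max"),
                     ~ fit_gain_model(pair, .x, n_starts = n_starts))
  names(fits) <- purrr::map_chr(fits, "label")
  va <- purrr::map_dbl(fits, "var_accounted")
  # precedence order is the order of `fits`; strictly better needed to displace
  best_i <- 1L
  for (i in 2:3) if (va[i] > va[best_i] + 1e-9) best_i <- i
  margin <- va[best_i] - max(va[-best_i])
  structure(
    list(fits = fits, best = names(fits)[best_i],
         var_accounted = va, margin = unname(margin)),
    class = "gain_classification"
  )
}

#' @export
print.gain_classification <- function(x, ...) {
  cat(sprintf("<gain_classification> best: %s (margin %.4f)\n", x$best, x$margin))
  for (f in x$fits) {
    cat(sprintf("  %-16s var accounted %.4f\n", f$label, f$var_accounted))
  }
  invisible(x)
}

#' Tidy attention-effect fits
#'
#' `tidy()` returns one row per fitted attention-effect model with its
#' parameters and variance accounted for; `glance()` returns a one-row
#' summary with the winning label and margin.
#'
#' @param x A `gain_fit` or `gain_classification`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gain_fit
#' @export
tidy.gain_fit <- function(x, ...) {
  tibble::tibble(
    model = x$label, free_param = x$free_param,
    r_max = x$shared[["r_max"]], c50 = x$shared[["c50"]],
    n = x$shared[["n"]], r_offset = x$shared[["r_offset"]],
    attended_value = x$attended_value,
    var_accounted = x$var_accounted, rss = x$rss
  )
}

#' @rdname tidy.gain_fit
#' @method tidy gain_classification
#' @export
tidy.gain_classification <- function(x, ...) {
  dplyr::mutate(purrr::map_dfr(x$fits, tidy),
                best = .data$model == x$best)
}

#' @rdname tidy.gain_fit
#' @method glance gain_classification
#' @export
glance.gain_classification <- function(x, ...) {
  tibble::tibble(best = x$best, margin = x$margin,
                 var_accounted_best = max(x$var_accounted))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
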