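#' Eccentricity-binned spatial profile of a voxel attribute
#'
#' Bins voxels by eccentricity relative to the grating center into 17
#' equal-width 1-degree bins spanning -8.5 to +8.5 degrees and returns the
#' per-bin mean of the requested attribute. When a `subject` column is
#' present, binning is done within subject and bin means are averaged
#' across subjects with equal weight, matching a group analysis in which
#' profiles are averaged across subjects before fitting. Voxels outside
#' the binned range, or with a missing attribute value, are dropped.
#'
#' @param voxels Voxel table with `eccentricity`, the attribute column, and
#'   optionally `subject`.
#' @param attribute Name of the attribute column (e.g.
#'   `"contrast_sensitivity"`, `"cue_sensitivity"`, `"amplitude"`).
#' @param center Grating-center eccentricity in degrees (e.g. from
#'   [locate_grating_center()]); default 0 if eccentricities are already
#'   relative.
#' @param n_bins Number of bins (default 17).
#' @param bin_width Bin width in degrees (default 1).
#' @return A `spatial_profile` tibble: `bin_center`, `mean`, `count`
#'   (voxels pooled over subjects), with attribute `attribute`.
#' @export
bin_profile <- function(voxels, attribute, center = 0, n_bins = 17,
                        bin_width = 1) {
  if (!attribute %in% names(voxels)) {
    stop("Attribute column `", attribute, "` not found.", call. = FALSE)
  }
  half_span <- n_bins * bin_width / 2
  centers <- seq(-half_span + bin_width / 2, half_span - bin_width / 2,
                 by = bin_width)
  rel <- voxels$eccentricity - center
  val <- voxels[[attribute]]
  keep <- !is.na(val) & rel >= -half_span & rel < half_span
  if (!any(keep)) stop("No voxels fall inside the binned range.", call. = FALSE)
  idx <- floor((rel[keep] + half_span) / bin_width) + 1L
  subj <- if ("subject" %in% names(voxels)) as.character(voxels$subject[keep])
          else rep("all", sum(keep))
  val <- val[keep]
  per_subj <- vapply(split(seq_along(val), subj), function(ii) {
    s <- c(bin_sums(idx[ii], val[ii], n_bins), tabulate(idx[ii], n_bins))
    s
  }, numeric(2 * n_bins))
  sums <- per_subj[seq_len(n_bins), , drop = FALSE]
  counts <- per_subj[n_bins + seq_len(n_bins), , drop = FALSE]
  means <- sums / counts               # NaN where a subject has an empty bin
  means[counts == 0] <- NA_real_
  out <- tibble::tibble(
    bin_center = centers,
    mean = rowMeans(means, na.rm = TRUE),
    count = as.integer(rowSums(counts))
  )
  out$mean[out$count == 0] <- NA_real_
  attr(out, "attribute") <- attribute
  class(out) <- c("spatial_profile", class(out))
  out
}

#' @noRd
bin_sums <- function(idx, val, n_bins) {
  s <- numeric(n_bins)
  r <- rowsum(val, idx)
  s[as.integer(rownames(r))] <- r[, 1]
  s
}

#' Fit a Gaussian model to a binned spatial profile
#'
#' `model = "single"`: one Gaussian with mean fixed at 0 degrees and offset
#' fixed at 0; the amplitude and standard deviation are fit. Used for the
#' contrast- and cue-sensitivity profiles, whose fitted standard deviations
#' measure the stimulus-drive and attention-field size.
#'
#' `model = "sum_of_two"`: sum of two Gaussians plus an offset; the first
#' accounts for foveal activity (mean constrained below -2 degrees, i.e.
#' foveal to the grating), the second for the stimulus response (mean fixed
#' at 0). Amplitudes, standard deviations, means (where free) and the
#' offset are fit. Used for the response-amplitude profile.
#'
#' Fitting is least squares on the non-empty bin means. The amplitudes and
#' offset enter linearly and are profiled out; the remaining nonlinear
#' parameters are optimized from multiple deterministic starts.
#'
#' @param profile A `spatial_profile` from [bin_profile()], or any tibble
#'   with `bin_center` and `mean` columns.
#' @param model `"single"` or `"sum_of_two"`.
#' @return A `gaussian_profile_fit` list: `model`, `amplitude`, `sigma`,
#'   `mean`, `offset` (vectors of length 1 or 2; second component is the
#'   stimulus Gaussian in the two-Gaussian model), `r2`, `rss`, `n_bins`.
#' @export
fit_spatial_gaussian <- function(profile, model = c("single", "sum_of_two")) {
  model <- match.arg(model)
  x <- profile$bin_center
  y <- profile$mean
  ok <- !is.na(y)
  x <- x[ok]; y <- y[ok]
  min_bins <- if (model == "single") 6L else 8L
  if (length(x) < min_bins) {
    stop("Need at least ", min_bins, " non-empty bins for the ", model,
         " model.", call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  if (model == "single") {
    fit <- fit_single_gaussian_fixed(x, y)
    out <- list(model = model, amplitude = fit$amplitude, sigma = fit$sigma,
                mean = 0, offset = 0, rss = fit$rss)
  } else {
    fit <- fit_two_gaussians(x, y)
    if (is.null(fit)) {
      stop("Two-Gaussian fit failed to converge from all starts.", call. = FALSE)
    }
    out <- list(model = model, amplitude = fit$amplitude, sigma = fit$sigma,
                mean = fit$mean, offset = fit$offset, rss = fit$rss)
  }
  out$r2 <- if (sst > 0) 1 - out$rss / sst else NA_real_
  out$n_bins <- length(x)
  structure(out, class = "gaussian_profile_fit")
}

# single zero-mean zero-offset Gaussian: amplitude is linear in the basis,
# leaving a 1-D profile-likelihood search over sigma
#' @noRd
fit_single_gaussian_fixed <- function(x, y, sigma_range = c(0.2, 30)) {
  rss_of <- function(s) {
    g <- exp(-x^2 / (2 * s^2))
    den <- sum(g * g)
    a <- sum(g * y) / den
    sum((y - a * g)^2)
  }
  # coarse log-spaced scan to bracket the global minimum, then refine
  scan <- exp(seq(log(sigma_range[1]), log(sigma_range[2]), length.out = 25))
  vals <- vapply(scan, rss_of, numeric(1))
  i <- which.min(vals)
  bracket <- c(scan[max(1, i - 1)], scan[min(length(scan), i + 1)])
  opt <- stats::optimize(rss_of, bracket, tol = 1e-7)
  s <- opt$minimum
  g <- exp(-x^2 / (2 * s^2))
  a <- sum(g * y) / sum(g * g)
  list(amplitude = a, sigma = s, rss = opt$objective)
}

# sum of two Gaussians + offset; means: first free (< -2), second fixed 0;
# linear parameters (two amplitudes, offset) profiled out
#' @noRd
fit_two_gaussians <- function(x, y) {
  design <- function(p) {
    cbind(exp(-(x - p[1])^2 / (2 * p[2]^2)), exp(-x^2 / (2 * p[3]^2)), 1)
  }
  obj <- function(p) {
    G <- design(p)
    b <- tryCatch(qr.coef(qr(G), y), error = function(e) NULL)
    if (is.null(b) || any(!is.finite(b))) return(sum(y^2) * 10)
    sum((y - G %*% b)^2)
  }
  starts <- tidyr::expand_grid(m1 = c(-6, -4, -8), s1 = c(1.5, 2.5),
                               s2 = c(1.5, 2.5, 4))
  lower <- c(min(x) - 2, 0.3, 0.3)
  upper <- c(-2, 15, 15)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(NULL)
  G <- design(best$par)
  b <- qr.coef(qr(G), y)
  list(amplitude = c(b[1], b[2]), sigma = c(best$par[2], best$par[3]),
       mean = c(best$par[1], 0), offset = b[3], rss = best$value)
}

#' @export
print.gaussian_profile_fit <- function(x, ...) {
  cat(sprintf("<gaussian_profile_fit %s> r2 %.3f\n", x$model, x$r2))
  for (i in seq_along(x$sigma)) {
    cat(sprintf("  component %d: amplitude %.4g, mean %.3g, sigma %.4g\n",
                i, x$amplitude[i], x$mean[i], x$sigma[i]))
  }
  if (any(x$offset != 0)) cat(sprintf("  offset %.4g\n", x$offset[1]))
  invisible(x)
}

#' @rdname tidy.gain_fit
#' @method tidy gaussian_profile_fit
#' @export
tidy.gaussian_profile_fit <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$sigma),
    amplitude = x$amplitude, mean = x$mean, sigma = x$sigma,
    offset = rep(x$offset, length.out = length(x$sigma))
  )
}

#' @rdname tidy.gain_fit
#' @method glance gaussian_profile_fit
#' @export
glance.gaussian_profile_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r2 = x$r2, rss = x$rss, n_bins = x$n_bins)
}

#' Plot a spatial profile with an optional Gaussian fit
#'
#' @param object A `spatial_profile`.
#' @param fit Optional `gaussian_profile_fit` overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spatial_profile
#' @export
autoplot.spatial_profile <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$bin_center, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "eccentricity relative to grating center (deg)",
                  y = attr(object, "attribute") %||% "mean") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xx <- seq(min(object$bin_center), max(object$bin_center), length.out = 200)
    yy <- rowSums(vapply(seq_along(fit$sigma), function(i) {
      fit$amplitude[i] * exp(-(xx - fit$mean[i])^2 / (2 * fit$sigma[i]^2))
    }, numeric(length(xx)))) + fit$offset[1]
    p <- p + ggplot2::geom_line(data = tibble::tibble(bin_center = xx, mean = yy),
                                colour = "#0072b2")
  }
  p
}
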