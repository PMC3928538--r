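#' @keywords internal
#' @noRd
nma_grid <- function(config) {
  x <- seq(-config$space_extent, config$space_extent, by = config$space_step)
  theta <- seq(-90, 90 - config$orientation_step, by = config$orientation_step)
  list(x = x, theta = theta)
}

# circular orientation distance with period 180 degrees
#' @noRd
orientation_distance <- function(theta, ref) {
  d <- (theta - ref) %% 180
  pmin(d, 180 - d)
}

#' @noRd
new_drive_field <- function(values, kind, grid) {
  structure(values, kind = kind, x = grid$x, theta = grid$theta,
            class = c("drive_field", "matrix", "array"))
}

#' @export
print.drive_field <- function(x, ...) {
  cat(sprintf("<drive_field kind=%s> %d x-points x %d orientations, range [%g, %g]\n",
              attr(x, "kind"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Excitatory stimulus-drive
#'
#' Computes the feed-forward stimulus-drive \eqn{E(x, \theta)}: each model
#' neuron, indexed by receptive-field center \eqn{x} and preferred
#' orientation \eqn{\theta}, receives drive from each grating equal to its
#' contrast times a Gaussian orientation-tuning factor (SD `e_theta_sd`,
#' circular distance with period 180) times the grating's rectangular
#' spatial envelope smoothed by the receptive-field Gaussian (SD
#' `e_space_sd`). Units are percent contrast; the modifiable baseline is
#' added later, in [model_response()].
#'
#' @param config An [nma_config()].
#' @param stimulus A [stimulus_spec()].
#' @return A `drive_field` matrix (space x orientation) of nonnegative drive
#'   values with attributes `x` and `theta` holding the grid axes.
#' @export
#' @examples
#' E <- stimulus_drive(nma_config(), stimulus_spec(contrast = 50))
#' max(E)
stimulus_drive <- function(config, stimulus) {
  stopifnot(inherits(config, "nma_config"))
  if (!inherits(stimulus, "stimulus_spec")) stimulus <- stimulus_spec_as(stimulus)
  grid <- nma_grid(config)
  E <- matrix(0, nrow = length(grid$x), ncol = length(grid$theta))
  for (g in seq_len(nrow(stimulus))) {
    sp <- grating_spatial_profile(
      grid$x, stimulus$center_x[g], stimulus$full_width[g], config$e_space_sd
    )
    d <- orientation_distance(grid$theta, stimulus$orientation[g])
    or <- exp(-d^2 / (2 * config$e_theta_sd^2))
    E <- E + stimulus$contrast[g] * outer(sp, or)
  }
  new_drive_field(E, "excitatory", grid)
}

# rectangular window of the stated full width convolved with the
# receptive-field Gaussian; unit height in the interior of a wide grating
#' @noRd
grating_spatial_profile <- function(x, center, full_width, sd) {
  lo <- center - full_width / 2
  hi <- center + full_width / 2
  stats::pnorm((x - lo) / sd) - stats::pnorm((x - hi) / sd)
}

#' @noRd
stimulus_spec_as <- function(x) {
  if (is.data.frame(x) &&
      all(c("center_x", "full_width", "orientation", "contrast") %in% names(x))) {
    return(stimulus_spec(x$center_x, x$full_width, x$orientation, x$contrast))
  }
  stop("`stimulus` must be a stimulus_spec().", call. = FALSE)
}

#' Fitted spatial size of the stimulus-drive
#'
#' The attention-field width is specified relative to the spatial size of
#' the stimulus-drive. Size is defined, as in the population-imaging
#' analysis, as the standard deviation of a Gaussian fitted by least squares
#' to the spatial profile of \eqn{E(x, \theta)} at the stimulus orientation.
#'
#' @param config An [nma_config()].
#' @param stimulus A [stimulus_spec()].
#' @return The fitted SD in degrees visual angle.
#' @export
#' @examples
#' stimulus_drive_sd(nma_config(), stimulus_spec())
stimulus_drive_sd <- function(config, stimulus) {
  E <- stimulus_drive(config, stimulus)
  grid <- list(x = attr(E, "x"), theta = attr(E, "theta"))
  itheta <- which.max(apply(unclass(E), 2, max))
  profile <- unclass(E)[, itheta]
  if (max(profile) <= 0) stop("Stimulus drive is identically zero; size undefined.",
                              call. = FALSE)
  fit_gaussian_1d(grid$x, profile)$sigma
}

# unconstrained 1-D Gaussian fit (amplitude, mean, sigma), moment-started,
# refined by variable projection over (mean, sigma)
#' @noRd
fit_gaussian_1d <- function(x, y) {
  w <- pmax(y, 0)
  mu0 <- sum(x * w) / sum(w)
  sd0 <- sqrt(sum((x - mu0)^2 * w) / sum(w))
  obj <- function(p) {
    g <- exp(-(x - p[1])^2 / (2 * p[2]^2))
    a <- sum(g * y) / sum(g * g)
    sum((y - a * g)^2)
  }
  fit <- stats::optim(c(mu0, max(sd0, 1e-3)), obj, method = "L-BFGS-B",
                      lower = c(min(x), diff(range(x)) / length(x) / 10),
                      upper = c(max(x), diff(range(x))))
  g <- exp(-(x - fit$par[1])^2 / (2 * fit$par[2]^2))
  a <- sum(g * y) / sum(g * g)
  list(amplitude = a, mean = fit$par[1], sigma = fit$par[2], rss = fit$value)
}

#' Attention-field gain
#'
#' The attentional gain applied multiplicatively to the stimulus-drive. In
#' `"spatial"` mode the gain is \eqn{1 + (g_{peak}-1)\,
#' \exp(-(x-x_0)^2 / (2 (r\,s)^2))} where \eqn{s} is the stimulus-drive
#' spatial SD and \eqn{r} the attention-field/stimulus-drive size ratio,
#' constant across orientation. In `"spatial_and_feature"` mode the bump is
#' additionally scaled by a Gaussian in orientation distance from the
#' attended feature. With `mode = "none"` the gain is identically 1.
#'
#' @param config An [nma_config()].
#' @param attn An [attention_spec()].
#' @param stimulus_spatial_sd Spatial SD of the stimulus-drive in degrees,
#'   as returned by [stimulus_drive_sd()].
#' @return A `drive_field` of kind `"gain"` (values >= 1).
#' @export
attention_gain <- function(config, attn, stimulus_spatial_sd) {
  stopifnot(inherits(config, "nma_config"), inherits(attn, "attention_spec"))
  grid <- nma_grid(config)
  if (attn$mode == "none") {
    return(new_drive_field(matrix(1, length(grid$x), length(grid$theta)),
                           "gain", grid))
  }
  if (!is.numeric(stimulus_spatial_sd) || stimulus_spatial_sd <= 0) {
    stop("`stimulus_spatial_sd` must be positive.", call. = FALSE)
  }
  af_sd <- attn$ratio * stimulus_spatial_sd
  bump_x <- exp(-(grid$x - attn$center_x)^2 / (2 * af_sd^2))
  bump_t <- if (attn$mode == "spatial_and_feature") {
    d <- orientation_distance(grid$theta, attn$feature_center)
    exp(-d^2 / (2 * attn$feature_sd^2))
  } else {
    rep(1, length(grid$theta))
  }
  gain <- 1 + (config$attention_peak_gain - 1) * outer(bump_x, bump_t)
  new_drive_field(gain, "gain", grid)
}

#' Suppressive drive
#'
#' Pools the attention-modulated stimulus-drive over the suppressive
#' kernel: uniformly over all preferred orientations, and over space with a
#' Gaussian of SD `s_space_sd`. Spatial pooling weights are renormalized at
#' each position so that a spatially uniform input of value \eqn{v} yields a
#' suppressive drive of exactly \eqn{v} everywhere (the discrete kernel
#' integrates to one over the simulated window). The result is constant
#' across orientation.
#'
#' @param modulated A `drive_field`: the attention-modulated excitatory
#'   drive, `gain * (E + baseline_mod)`. The pool must include the attention
#'   modulation -- neurons whose gain was raised by the attention field
#'   contribute more suppression.
#' @param config An [nma_config()].
#' @return A `drive_field` of kind `"suppressive"`, constant over
#'   orientation.
#' @export
suppressive_drive <- function(modulated, config) {
  stopifnot(inherits(modulated, "drive_field"), inherits(config, "nma_config"))
  grid <- list(x = attr(modulated, "x"), theta = attr(modulated, "theta"))
  pooled_theta <- rowMeans(unclass(modulated))
  W <- suppressive_weights(grid$x, config$s_space_sd)
  s_x <- as.numeric(W %*% pooled_theta)
  S <- matrix(s_x, nrow = length(grid$x), ncol = length(grid$theta))
  new_drive_field(S, "suppressive", grid)
}

# row-normalized Gaussian weight matrix over the spatial grid
#' @noRd
suppressive_weights <- function(x, sd) {
  K <- exp(-outer(x, x, "-")^2 / (2 * sd^2))
  K / rowSums(K)
}

#' Normalization-model response field
#'
#' Evaluates the model response of every neuron on the grid: the
#' attention-modulated drive `gain * (E + baseline_mod)` is divided by the
#' suppressive drive plus the semisaturation constant `sigma`, and the
#' result is thresholded (half-wave rectified after subtracting
#' `spike_threshold`) to mimic the spiking threshold.
#'
#' @inheritParams stimulus_drive
#' @param attn An [attention_spec()]; `mode = "none"` gives the unattended
#'   response.
#' @param stimulus_spatial_sd Optional spatial SD of the stimulus-drive in
#'   degrees, fixing the attention-field width. Defaults to measuring it
#'   from `stimulus` via [stimulus_drive_sd()]; supply it explicitly when
#'   evaluating a contrast ladder (including zero contrast) under a fixed
#'   attention field.
#' @return A `drive_field`-like response matrix of class `response_field`
#'   (space x orientation), all values >= 0.
#' @export
#' @examples
#' R <- model_response(nma_config(), stimulus_spec(contrast = 50),
#'                     attention_spec("none"))
model_response <- function(config, stimulus, attn, stimulus_spatial_sd = NULL) {
  stopifnot(inherits(config, "nma_config"))
  E <- stimulus_drive(config, stimulus)
  grid <- list(x = attr(E, "x"), theta = attr(E, "theta"))
  sd_stim <- if (attn$mode == "none") {
    NULL
  } else {
    stimulus_spatial_sd %||% stimulus_drive_sd(config, stimulus)
  }
  gain <- attention_gain(config, attn, stimulus_spatial_sd = sd_stim %||% 1)
  modulated <- new_drive_field(
    unclass(gain) * (unclass(E) + config$baseline_mod), "modulated", grid
  )
  S <- suppressive_drive(modulated, config)
  R <- pmax(unclass(modulated) / (unclass(S) + config$sigma) - config$spike_threshold, 0)
  structure(R, x = grid$x, theta = grid$theta,
            class = c("response_field", "drive_field", "matrix", "array"))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
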