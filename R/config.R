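#' Model configuration for the normalization model of attention
#'
#' Collects every parameter of the divisive-normalization response equation
#' together with the discretization of the simulated space. The model lives
#' on a 1-D spatial axis (degrees of visual angle; the population analysis
#' collapses to radial eccentricity) crossed with preferred orientation on
#' \eqn{[-90, 90)} degrees.
#'
#' @param space_extent Half-width of the simulated spatial axis in degrees
#'   visual angle; the grid runs from `-space_extent` to `+space_extent`.
#' @param space_step Spatial grid step in degrees. Must resolve the
#'   excitatory spatial tuning (`space_step < e_space_sd`).
#' @param orientation_step Orientation grid step in degrees; the orientation
#'   axis covers \eqn{[-90, 90)} and wraps with period 180.
#' @param e_space_sd Standard deviation, in degrees, of the Gaussian spatial
#'   tuning of the excitatory stimulus-drive (default 0.75, a published
#'   population receptive-field size for V1 at parafoveal eccentricity).
#' @param e_theta_sd Orientation tuning width in degrees, defined as the
#'   half-width at 60.7% of maximum -- for a Gaussian this equals its
#'   standard deviation (default 60).
#' @param s_space_sd Standard deviation, in degrees, of the Gaussian spatial
#'   kernel of the suppressive pool (default 20).
#' @param sigma Semisaturation constant of the normalization equation, in
#'   percent contrast; sets the horizontal position (contrast-gain) of the
#'   contrast-response function. Must be positive.
#' @param baseline_mod Modifiable baseline in percent contrast (default
#'   5e-7): a contrast-equivalent input added to the stimulus-drive that is
#'   present regardless of the stimulus and is subject to attentional gain.
#' @param spike_threshold Response threshold subtracted before half-wave
#'   rectification (default 0, pure rectification).
#' @param attention_peak_gain Multiplicative gain at the center of the
#'   attention field (dimensionless, > 1; default 4).
#'
#' @return An object of class `nma_config`: a validated list of the above.
#' @seealso [stimulus_spec()], [attention_spec()], [model_response()]
#' @export
#' @examples
#' cfg <- nma_config()
#' cfg$sigma
nma_config <- function(space_extent = 15,
                       space_step = 0.1,
                       orientation_step = 3,
                       e_space_sd = 0.75,
                       e_theta_sd = 60,
                       s_space_sd = 20,
                       sigma = 3,
                       baseline_mod = 5e-7,
                       spike_threshold = 0,
                       attention_peak_gain = 4) {
  cfg <- list(
    space_extent = space_extent, space_step = space_step,
    orientation_step = orientation_step,
    e_space_sd = e_space_sd, e_theta_sd = e_theta_sd,
    s_space_sd = s_space_sd, sigma = sigma,
    baseline_mod = baseline_mod, spike_threshold = spike_threshold,
    attention_peak_gain = attention_peak_gain
  )
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number.", call. = FALSE)
    }
  }
  if (any(c(cfg$e_space_sd, cfg$e_theta_sd, cfg$s_space_sd) <= 0)) {
    stop("All tuning/kernel standard deviations must be positive.", call. = FALSE)
  }
  if (cfg$sigma <= 0) stop("`sigma` must be positive.", call. = FALSE)
  if (cfg$baseline_mod < 0) stop("`baseline_mod` must be nonnegative.", call. = FALSE)
  if (cfg$space_step <= 0 || cfg$orientation_step <= 0) {
    stop("Grid steps must be positive.", call. = FALSE)
  }
  if (cfg$space_step >= cfg$e_space_sd) {
    stop("Grid too coarse: `space_step` must be smaller than `e_space_sd` ",
         "to resolve the excitatory spatial tuning.", call. = FALSE)
  }
  if (cfg$attention_peak_gain <= 1) {
    stop("`attention_peak_gain` must exceed 1.", call. = FALSE)
  }
  structure(cfg, class = "nma_config")
}

#' @export
print.nma_config <- function(x, ...) {
  cat("<nma_config>\n")
  cat(sprintf("  space  : [%g, %g] deg, step %g\n",
              -x$space_extent, x$space_extent, x$space_step))
  cat(sprintf("  theta  : [-90, 90) deg, step %g\n", x$orientation_step))
  cat(sprintf("  tuning : e_space_sd %g, e_theta_sd %g, s_space_sd %g\n",
              x$e_space_sd, x$e_theta_sd, x$s_space_sd))
  cat(sprintf("  model  : sigma %g, baseline_mod %g, threshold %g, peak gain %g\n",
              x$sigma, x$baseline_mod, x$spike_threshold, x$attention_peak_gain))
  invisible(x)
}

#' Stimulus specification
#'
#' One or more oriented contrast gratings placed on the 1-D spatial axis.
#' Each grating has a rectangular spatial envelope of the stated full-width;
#' the excitatory drive smooths this envelope with the receptive-field
#' Gaussian.
#'
#' @param center_x Grating center(s), degrees visual angle.
#' @param full_width Full spatial width(s) in degrees (default 6, matching a
#'   3 degree-radius grating).
#' @param orientation Grating orientation(s), degrees in \eqn{[-90, 90)}.
#' @param contrast Contrast(s) in percent, each in \eqn{[0, 100]}.
#'
#' @return A `stimulus_spec`: a tibble with one row per grating.
#' @export
#' @examples
#' stimulus_spec(contrast = 50)
stimulus_spec <- function(center_x = 0, full_width = 6, orientation = 0,
                          contrast = 100) {
  out <- tibble::tibble(
    center_x = as.numeric(center_x),
    full_width = as.numeric(full_width),
    orientation = as.numeric(orientation),
    contrast = as.numeric(contrast)
  )
  if (nrow(out) < 1L) stop("At least one grating is required.", call. = FALSE)
  if (any(!is.finite(unlist(out)))) stop("Stimulus fields must be finite.", call. = FALSE)
  if (any(out$contrast < 0 | out$contrast > 100)) {
    stop("Contrasts must lie in [0, 100] percent.", call. = FALSE)
  }
  if (any(out$full_width <= 0)) stop("`full_width` must be positive.", call. = FALSE)
  class(out) <- c("stimulus_spec", class(out))
  out
}

#' Attention field specification
#'
#' The attention field is a multiplicative gain applied to the
#' stimulus-drive: a spatial Gaussian bump of peak `attention_peak_gain`
#' (from [nma_config()]) whose standard deviation is `ratio` times the
#' fitted spatial size of the stimulus-drive. In `"spatial_and_feature"`
#' mode the bump is additionally restricted along preferred orientation.
#'
#' @param mode One of `"none"` (unit gain everywhere), `"spatial"`, or
#'   `"spatial_and_feature"`.
#' @param center_x Center of the attention field in degrees (default 0, the
#'   stimulus center).
#' @param ratio Attention-field SD divided by stimulus-drive spatial SD
#'   (dimensionless, default 1.4 -- the value measured from cortical
#'   cue- vs contrast-sensitivity profiles).
#' @param feature_center Attended orientation in degrees (used only in
#'   `"spatial_and_feature"` mode).
#' @param feature_sd Orientation SD of the featural restriction in degrees
#'   (default 60, matching the excitatory orientation tuning width).
#'
#' @return An object of class `attention_spec`.
#' @export
#' @examples
#' attention_spec("spatial", ratio = 1.4)
attention_spec <- function(mode = c("spatial", "none", "spatial_and_feature"),
                           center_x = 0, ratio = 1.4,
                           feature_center = 0, feature_sd = 60) {
  mode <- match.arg(mode)
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) || ratio <= 0) {
    stop("`ratio` must be a single positive number.", call. = FALSE)
  }
  if (feature_sd <= 0) stop("`feature_sd` must be positive.", call. = FALSE)
  structure(
    list(mode = mode, center_x = center_x, ratio = ratio,
         feature_center = feature_center, feature_sd = feature_sd),
    class = "attention_spec"
  )
}

#' @export
print.attention_spec <- function(x, ...) {
  cat(sprintf("<attention_spec> mode=%s center=%g ratio=%g", x$mode,
              x$center_x, x$ratio))
  if (x$mode == "spatial_and_feature") {
    cat(sprintf(" feature_center=%g feature_sd=%g", x$feature_center, x$feature_sd))
  }
  cat("\n")
  invisible(x)
}
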