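#' Default contrast ladder
#'
#' Zero contrast plus `n` log-spaced contrasts between `from` and `to`
#' percent.
#'
#' @param n Number of nonzero contrasts (default 12).
#' @param from,to Range of the nonzero contrasts in percent (defaults 0.5
#'   and 100).
#' @param include_zero Include the 0% contrast point (default `TRUE`).
#' @return Sorted numeric vector of contrasts in percent.
#' @export
#' @examples
#' contrast_ladder()
contrast_ladder <- function(n = 12, from = 0.5, to = 100, include_zero = TRUE) {
  stopifnot(n >= 2, from > 0, to > from)
  lad <- exp(seq(log(from), log(to), length.out = n))
  lad[c(1, n)] <- c(from, to)   # exact endpoints, free of log/exp round-off
  if (include_zero) lad <- c(0, lad)
  lad
}

#' Contrast-response functions with and without attention
#'
#' Runs the normalization model across a contrast ladder, once with the
#' given attention field and once with attention off, and reports either a
#' single model neuron's response or the population average (the unweighted
#' mean response over every neuron on the space x orientation grid --
#' the quantity a population-scale measurement such as fMRI reflects).
#'
#' @param config An [nma_config()].
#' @param stimulus_template A [stimulus_spec()]; its `contrast` column is
#'   overwritten by each ladder value (all gratings share the ladder
#'   contrast). The attention-field width is fixed from this template.
#' @param attn An [attention_spec()].
#' @param contrasts Ascending contrast ladder in percent (default
#'   [contrast_ladder()]).
#' @param scope `"population_average"` or `"single_neuron"`.
#' @param x,theta Receptive-field center and preferred orientation of the
#'   probed neuron when `scope = "single_neuron"`; snapped to the nearest
#'   grid node within half a grid step (off-grid requests error).
#' @return A tibble of class `contrast_response_pair` with columns
#'   `contrast`, `r_unattended`, `r_attended`, `scope`, and attributes
#'   recording the configuration.
#' @export
#' @examples
#' cfg <- nma_config()
#' pair <- contrast_response(cfg, stimulus_spec(), attention_spec("spatial"),
#'                           contrasts = c(0, 10, 50, 100))
contrast_response <- function(config, stimulus_template, attn,
                              contrasts = contrast_ladder(),
                              scope = c("population_average", "single_neuron"),
                              x = 0, theta = 0) {
  scope <- match.arg(scope)
  stopifnot(inherits(config, "nma_config"))
  if (is.unsorted(contrasts)) {
    stop("`contrasts` must be sorted ascending.", call. = FALSE)
  }
  grid <- nma_grid(config)
  if (scope == "single_neuron") {
    ix <- nearest_index(grid$x, x, config$space_step)
    it <- nearest_index(grid$theta, theta, config$orientation_step)
  }
  template <- stimulus_template
  template$contrast <- max(template$contrast)
  sd_stim <- stimulus_drive_sd(config, template)
  none <- attention_spec("none")

  take <- function(R) {
    if (scope == "population_average") mean(R) else unclass(R)[ix, it]
  }
  vals <- purrr::map(contrasts, function(cc) {
    st <- stimulus_template
    st$contrast <- rep(cc, nrow(st))
    ru <- take(model_response(config, st, none))
    ra <- take(model_response(config, st, attn, stimulus_spatial_sd = sd_stim))
    c(ru, ra)
  })
  out <- tibble::tibble(
    contrast = as.numeric(contrasts),
    r_unattended = purrr::map_dbl(vals, 1),
    r_attended = purrr::map_dbl(vals, 2),
    scope = scope
  )
  attr(out, "config") <- config
  attr(out, "attn") <- attn
  attr(out, "stimulus_spatial_sd") <- sd_stim
  if (scope == "single_neuron") attr(out, "neuron") <- c(x = x, theta = theta)
  class(out) <- c("contrast_response_pair", class(out))
  out
}

#' @noRd
nearest_index <- function(axis, value, step) {
  i <- which.min(abs(axis - value))
  if (abs(axis[i] - value) > step / 2 + 1e-9) {
    stop("Requested neuron at ", value, " lies off the simulated grid.",
         call. = FALSE)
  }
  i
}

#' Write / read a contrast-response pair as CSV
#'
#' Plain-text interchange for contrast-response pairs: columns `contrast`,
#' `r_unattended`, `r_attended`, `scope` in that order, numbers written with
#' 12 significant digits.
#'
#' @param pair A `contrast_response_pair`.
#' @param path File path.
#' @return `write_contrast_response()` returns `path` invisibly;
#'   `read_contrast_response()` returns a `contrast_response_pair` tibble.
#' @export
write_contrast_response <- function(pair, path) {
  df <- as.data.frame(pair)[, c("contrast", "r_unattended", "r_attended", "scope")]
  for (nm in c("contrast", "r_unattended", "r_attended")) {
    df[[nm]] <- formatC(df[[nm]], digits = 12, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contrast_response
#' @export
read_contrast_response <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  class(out) <- c("contrast_response_pair", class(out))
  out
}

#' Plot a contrast-response pair
#'
#' Attended and unattended contrast-response functions on a logarithmic
#' contrast axis (the zero-contrast point, if present, is drawn at the
#' smallest nonzero contrast / 2).
#'
#' @param object A `contrast_response_pair`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contrast_response_pair
#' @export
autoplot.contrast_response_pair <- function(object, ...) {
  df <- tibble::as_tibble(object)
  nz <- df$contrast[df$contrast > 0]
  df$c_plot <- ifelse(df$contrast > 0, df$contrast, min(nz) / 2)
  long <- tidyr::pivot_longer(df, c("r_unattended", "r_attended"),
                              names_to = "condition", values_to = "response")
  long$condition <- factor(long$condition, c("r_unattended", "r_attended"),
                           c("unattended", "attended"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$c_plot, y = .data$response,
                                     colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(unattended = "black", attended = "red")) +
    ggplot2::labs(x = "contrast (%)", y = "model response",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
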