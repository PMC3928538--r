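#' Define a sweep over attention-field ratio and modifiable baseline
#'
#' The two key model parameters explored by the population analysis: the
#' ratio of attention-field to stimulus-drive size, and the amount of
#' baseline response subject to attentional modulation.
#'
#' @param ratios Positive ascending ratios; default 7 log-spaced values
#'   from 0.1 to 10.
#' @param baselines Nonnegative ascending modifiable-baseline levels in
#'   percent contrast; default `c(0, 1e-8, 5e-7, 1e-5, 1e-3)`.
#' @param mode Attention mode, `"spatial"` or `"spatial_and_feature"`.
#' @param scope `"well_tuned_neuron"` (grid node nearest the stimulus
#'   center and orientation) or `"population_average"`.
#' @return A `sweep_grid` list.
#' @export
sweep_grid <- function(ratios = 10^seq(-1, 1, length.out = 7),
                       baselines = c(0, 1e-8, 5e-7, 1e-5, 1e-3),
                       mode = c("spatial", "spatial_and_feature"),
                       scope = c("well_tuned_neuron", "population_average")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (any(ratios <= 0) || is.unsorted(ratios, strictly = TRUE)) {
    stop("`ratios` must be positive and strictly ascending.", call. = FALSE)
  }
  if (any(baselines < 0) || is.unsorted(baselines)) {
    stop("`baselines` must be nonnegative and ascending.", call. = FALSE)
  }
  structure(list(ratios = ratios, baselines = baselines, mode = mode,
                 scope = scope),
            class = "sweep_grid")
}

#' Sweep attention-field ratio and modifiable baseline
#'
#' For every (ratio, baseline) cell of the grid, computes the
#' attended/unattended contrast-response pair for the requested scope and
#' classifies the attention effect (contrast-gain / response-gain /
#' additive-offset). Cells in which attention leaves the response exactly
#' unchanged are recorded as `"no-effect"` rather than failing.
#'
#' @param config An [nma_config()]; its `baseline_mod` is overridden per
#'   cell, everything else is held fixed.
#' @param stimulus A [stimulus_spec()].
#' @param grid A [sweep_grid()].
#' @param contrasts Contrast ladder (default [contrast_ladder()]).
#' @return A `sweep_result` tibble with one row per cell: `ratio`,
#'   `baseline`, `best`, `margin`, per-model variance accounted for
#'   (`va_additive_offset`, `va_contrast_gain`, `va_response_gain`), and a
#'   list-column `pair` with the underlying contrast-response tibble.
#'   Attributes `config` and `grid` carry the full configuration.
#' @export
run_sweep <- function(config, stimulus, grid, contrasts = contrast_ladder()) {
  stopifnot(inherits(config, "nma_config"), inherits(grid, "sweep_grid"))
  attn_mode <- if (grid$mode == "spatial") "spatial" else "spatial_and_feature"
  scope <- if (grid$scope == "well_tuned_neuron") "single_neuron"
           else "population_average"
  stim_center <- stimulus$center_x[which.max(stimulus$contrast)]
  stim_orient <- stimulus$orientation[which.max(stimulus$contrast)]
  cells <- tidyr::expand_grid(baseline = grid$baselines, ratio = grid$ratios)
  rows <- purrr::pmap(cells, function(baseline, ratio) {
    cfg <- config
    cfg$baseline_mod <- baseline
    attn <- attention_spec(attn_mode, center_x = stim_center, ratio = ratio,
                           feature_center = stim_orient)
    pair <- contrast_response(cfg, stimulus, attn, contrasts = contrasts,
                              scope = scope, x = stim_center,
                              theta = stim_orient)
    cl <- tryCatch(classify_attention_effect(pair), error = function(e) NULL)
    if (is.null(cl)) {
      tibble::tibble(ratio = ratio, baseline = baseline, best = "no-effect",
                     margin = NA_real_, va_additive_offset = NA_real_,
                     va_contrast_gain = NA_real_, va_response_gain = NA_real_,
                     pair = list(pair))
    } else {
      tibble::tibble(
        ratio = ratio, baseline = baseline, best = cl$best,
        margin = cl$margin,
        va_additive_offset = cl$var_accounted[["additive-offset"]],
        va_contrast_gain = cl$var_accounted[["contrast-gain"]],
        va_response_gain = cl$var_accounted[["response-gain"]],
        pair = list(pair)
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "grid") <- grid
  class(out) <- c("sweep_result", class(out))
  out
}

#' Summarize a sweep as label and margin maps
#'
#' @param result A `sweep_result` from [run_sweep()].
#' @return A tibble with one row per cell: `ratio`, `baseline`, `best`,
#'   `margin` (best-minus-runner-up variance accounted for; nonnegative).
#' @export
summarize_sweep <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  dplyr::select(tibble::as_tibble(result), "ratio", "baseline", "best", "margin")
}

#' Plot a sweep label map
#'
#' Tile map of the winning attention-effect label over the
#' ratio x baseline grid (log-spaced ratio axis; baselines as ordered
#' categories since they may include zero).
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- summarize_sweep(object)
  df$baseline <- factor(df$baseline, levels = sort(unique(df$baseline)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$baseline,
                                   fill = .data$best)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_manual(values = c(
      "contrast-gain" = "#d55e00", "response-gain" = "#009e73",
      "additive-offset" = "#0072b2", "no-effect" = "grey80"
    )) +
    ggplot2::labs(x = "attention-field / stimulus-drive size ratio",
                  y = "modifiable baseline (% contrast)",
                  fill = "best model") +
    ggplot2::theme_minimal()
}
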