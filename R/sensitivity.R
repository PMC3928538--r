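#' Per-voxel contrast-sensitivity, cue-sensitivity and amplitude
#'
#' Derives the three task-related voxel attributes from condition-wise
#' response amplitudes:
#' * `amplitude` -- mean response over all pedestal contrasts and cue
#'   conditions (% signal change);
#' * `contrast_sensitivity` -- slope of the voxel's contrast-response
#'   function (% signal change per % contrast): ordinary least-squares
#'   slope of the cue-averaged amplitude against pedestal contrast on a
#'   linear axis. Computed only for voxels whose amplitude-estimation
#'   `fit_r2` exceeds `r2_threshold`; others get `NA` and are counted in
#'   the `excluded` attribute;
#' * `cue_sensitivity` -- mean cued amplitude minus mean uncued amplitude,
#'   regardless of pedestal contrast (positive when cueing increased the
#'   response).
#'
#' @param voxels Voxel table: one row per voxel with columns `eccentricity`,
#'   `coherence`, `fit_r2`, and amplitude columns named
#'   `amp_c<contrast>_<cued|uncued>` for each pedestal contrast.
#' @param contrasts Pedestal contrasts in percent (default
#'   `c(12.5, 25, 50)`).
#' @param r2_threshold Amplitude-fit quality threshold for
#'   contrast-sensitivity (default 0.7).
#' @return The input tibble with `amplitude`, `contrast_sensitivity` and
#'   `cue_sensitivity` columns appended; attribute `excluded` holds the
#'   number of voxels whose contrast-sensitivity was withheld.
#' @export
voxel_sensitivities <- function(voxels, contrasts = c(12.5, 25, 50),
                                r2_threshold = 0.7) {
  cued_cols <- paste0("amp_c", contrasts, "_cued")
  uncued_cols <- paste0("amp_c", contrasts, "_uncued")
  missing_cols <- setdiff(c(cued_cols, uncued_cols, "fit_r2"), names(voxels))
  if (length(missing_cols) > 0) {
    stop("Voxel table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cued <- as.matrix(voxels[cued_cols])
  uncued <- as.matrix(voxels[uncued_cols])
  mean_amp <- (cued + uncued) / 2      # per-contrast, cue-averaged
  # closed-form OLS slope against the contrast axis
  cx <- contrasts - mean(contrasts)
  slope <- as.vector(mean_amp %*% cx) / sum(cx^2)
  keep <- voxels$fit_r2 > r2_threshold
  slope[!keep] <- NA_real_
  out <- dplyr::mutate(
    tibble::as_tibble(voxels),
    amplitude = rowMeans(cbind(cued, uncued)),
    contrast_sensitivity = slope,
    cue_sensitivity = rowMeans(cued) - rowMeans(uncued)
  )
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Contrast-sensitivity of voxels
#'
#' Ordinary least-squares slope of the cue-averaged response amplitude
#' against pedestal contrast; `NA` for voxels failing the amplitude-fit
#' quality threshold. See [voxel_sensitivities()] for the column contract.
#'
#' @inheritParams voxel_sensitivities
#' @return Numeric vector, one slope per voxel (% signal change / % contrast).
#' @export
contrast_sensitivity <- function(voxels, contrasts = c(12.5, 25, 50),
                                 r2_threshold = 0.7) {
  voxel_sensitivities(voxels, contrasts, r2_threshold)$contrast_sensitivity
}

#' Cue-sensitivity of voxels
#'
#' Mean cued minus mean uncued response amplitude, pooled over pedestal
#' contrasts.
#'
#' @inheritParams voxel_sensitivities
#' @return Numeric vector, one difference per voxel (% signal change).
#' @export
cue_sensitivity <- function(voxels, contrasts = c(12.5, 25, 50)) {
  cued_cols <- paste0("amp_c", contrasts, "_cued")
  uncued_cols <- paste0("amp_c", contrasts, "_uncued")
  missing_cols <- setdiff(c(cued_cols, uncued_cols), names(voxels))
  if (length(missing_cols) > 0) {
    stop("Voxel table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rowMeans(as.matrix(voxels[cued_cols])) -
    rowMeans(as.matrix(voxels[uncued_cols]))
}

#' Locate the grating center from localizer coherence
#'
#' Mean raw eccentricity of voxels whose localizer coherence exceeds the
#' threshold; used as the origin of the relative-eccentricity profiles.
#'
#' @param voxels Voxel table with `eccentricity` and `coherence` columns.
#' @param threshold Coherence threshold (default 0.5).
#' @return Eccentricity of the grating center in degrees.
#' @export
locate_grating_center <- function(voxels, threshold = 0.5) {
  keep <- voxels$coherence > threshold
  if (!any(keep)) {
    stop("No voxel has coherence above ", threshold,
         "; grating center undefined.", call. = FALSE)
  }
  mean(voxels$eccentricity[keep])
}
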