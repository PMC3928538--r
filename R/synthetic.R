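#' Parameters for the synthetic voxel-population generator
#'
#' Defines a voxel population whose task-related attributes carry the
#' spatial structure the profile analysis assumes: per-voxel expected
#' contrast-slope and cue-difference follow zero-mean-centered Gaussian
#' profiles of eccentricity with configurable widths, and the response
#' amplitude follows a sum of a foveal and a stimulus Gaussian. The
#' defaults mirror the widths estimated from cortex: cue-sensitivity SD
#' 4.92 degrees, contrast-sensitivity SD 3.44 degrees, amplitude components
#' with SDs 2.03 (foveal, mean -6 degrees) and 2.17 (stimulus).
#'
#' @param n_subjects Number of simulated subjects (default 5).
#' @param n_voxels Voxels per subject (default 2000).
#' @param ecc_range Relative-eccentricity range sampled uniformly
#'   (default `c(-8.5, 8.5)` degrees).
#' @param sigma_cue SD of the cue-sensitivity profile (default 4.92).
#' @param sigma_contrast SD of the contrast-sensitivity profile
#'   (default 3.44).
#' @param amp_foveal_mean,amp_foveal_sd Foveal amplitude component mean and
#'   SD (defaults -6 and 2.03 degrees).
#' @param amp_stim_sd Stimulus amplitude component SD (default 2.17).
#' @param peak_cue Peak cue-sensitivity (% signal change, default 0.3).
#' @param peak_contrast Peak contrast-sensitivity (% signal change per
#'   % contrast, default 0.02).
#' @param peak_amp_stim,peak_amp_foveal Peak amplitudes of the two
#'   amplitude components (% signal change, defaults 1.0 and 0.8).
#' @param noise_sd_amp Gaussian noise SD added to each condition amplitude
#'   (% signal change, default 0.1).
#' @param surround_amp Negative-surround amplitude: responses beyond the
#'   stimulus band are depressed by this amount (default 0 = off; the
#'   measured maps showed responses turning negative outside the stimulus
#'   band).
#' @param surround_edge Eccentricity beyond which the surround applies
#'   (default 3 degrees).
#' @param contrasts Pedestal contrasts (default `c(12.5, 25, 50)`).
#' @param coherence_in,coherence_out Mean localizer coherence inside/outside
#'   the stimulus band (defaults 0.8 and 0.2).
#' @param band_halfwidth Stimulus-band half-width for the coherence model
#'   (default 3 degrees).
#' @param fit_r2_mean Mean amplitude-fit quality (default 0.88; a small
#'   fraction of voxels falls below the 0.7 inclusion threshold).
#' @param seed Integer seed.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_subjects = 5, n_voxels = 2000,
                         ecc_range = c(-8.5, 8.5),
                         sigma_cue = 4.92, sigma_contrast = 3.44,
                         amp_foveal_mean = -6, amp_foveal_sd = 2.03,
                         amp_stim_sd = 2.17,
                         peak_cue = 0.3, peak_contrast = 0.02,
                         peak_amp_stim = 1.0, peak_amp_foveal = 0.8,
                         noise_sd_amp = 0.1,
                         surround_amp = 0, surround_edge = 3,
                         contrasts = c(12.5, 25, 50),
                         coherence_in = 0.8, coherence_out = 0.2,
                         band_halfwidth = 3,
                         fit_r2_mean = 0.88,
                         seed = 1) {
  p <- as.list(environment())
  stopifnot(p$n_voxels >= 1, p$n_subjects >= 1,
            p$sigma_cue > 0, p$sigma_contrast > 0,
            p$amp_foveal_sd > 0, p$amp_stim_sd > 0, p$noise_sd_amp >= 0)
  structure(p, class = "synth_params")
}

#' Generate a synthetic voxel table
#'
#' Draws voxel eccentricities uniformly over the configured range and
#' builds condition amplitudes `amp_c<contrast>_<cued|uncued>` such that
#' the pipeline's attribute definitions recover the generating spatial
#' profiles: the cue-averaged amplitude is linear in contrast with slope
#' equal to the voxel's expected contrast-sensitivity, and the cued-uncued
#' difference equals the voxel's expected cue-sensitivity, both Gaussian
#' profiles of eccentricity. Independent Gaussian noise is added to every
#' condition amplitude. Localizer coherence is high inside the stimulus
#' band and low outside. Fully reproducible from the seed.
#'
#' @param params A [synth_params()].
#' @return A tibble, one row per voxel: `subject`, `voxel`, `eccentricity`,
#'   `coherence`, `fit_r2`, and the six amplitude columns. The attribute
#'   `truth` carries the generating parameters and per-voxel expected
#'   attribute values (a tibble with `expected_contrast_sensitivity`,
#'   `expected_cue_sensitivity`, `expected_amplitude`).
#' @export
#' @examples
#' vox <- generate_voxels(synth_params(n_subjects = 2, n_voxels = 50))
#' dplyr::glimpse(vox)
generate_voxels <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)
  p <- params
  n_total <- p$n_subjects * p$n_voxels
  ecc <- stats::runif(n_total, p$ecc_range[1], p$ecc_range[2])
  subject <- rep(sprintf("s%02d", seq_len(p$n_subjects)), each = p$n_voxels)

  e_contrast <- p$peak_contrast * exp(-ecc^2 / (2 * p$sigma_contrast^2))
  e_cue <- p$peak_cue * exp(-ecc^2 / (2 * p$sigma_cue^2))
  e_amp <- p$peak_amp_foveal * exp(-(ecc - p$amp_foveal_mean)^2 /
                                     (2 * p$amp_foveal_sd^2)) +
    p$peak_amp_stim * exp(-ecc^2 / (2 * p$amp_stim_sd^2))
  if (p$surround_amp != 0) {
    e_amp <- e_amp - p$surround_amp * (abs(ecc) > p$surround_edge)
  }

  cbar <- mean(p$contrasts)
  amps <- list()
  for (ci in seq_along(p$contrasts)) {
    cc <- p$contrasts[ci]
    base <- e_amp + e_contrast * (cc - cbar)
    for (cond in c("cued", "uncued")) {
      sgn <- if (cond == "cued") 0.5 else -0.5
      amps[[paste0("amp_c", cc, "_", cond)]] <-
        base + sgn * e_cue + stats::rnorm(n_total, 0, p$noise_sd_amp)
    }
  }
  coherence <- pmin(pmax(
    ifelse(abs(ecc) <= p$band_halfwidth, p$coherence_in, p$coherence_out) +
      stats::rnorm(n_total, 0, 0.05), 0), 1)
  fit_r2 <- pmin(pmax(stats::rnorm(n_total, p$fit_r2_mean, 0.08), 0), 1)

  out <- tibble::tibble(
    subject = subject,
    voxel = sequence(rep(p$n_voxels, p$n_subjects)),
    eccentricity = ecc,
    coherence = coherence,
    fit_r2 = fit_r2,
    !!!amps
  )
  attr(out, "truth") <- list(
    params = params,
    per_voxel = tibble::tibble(
      subject = subject, voxel = out$voxel,
      expected_contrast_sensitivity = e_contrast,
      expected_cue_sensitivity = e_cue,
      expected_amplitude = e_amp
    )
  )
  out
}

#' Generate a synthetic voxel time series with known event amplitudes
#'
#' Builds a time series as the linear superposition of gamma-shaped
#' responses ([gamma_hrf()]) at the given condition onsets, plus an
#' optional sinusoidal localizer component and white noise. The generating
#' amplitudes are returned alongside so deconvolution can be validated
#' against ground truth.
#'
#' @param design Data frame with columns `condition` and `onset` (volume
#'   indices).
#' @param n_volumes Length of the series.
#' @param amplitudes Named vector of peak response amplitudes per condition.
#' @param tau,delay Gamma time constant and delay in volumes (defaults 1.2
#'   and 1).
#' @param localizer_amplitude,localizer_cycles Amplitude and cycles-per-scan
#'   of an added sinusoid (default 0 = none).
#' @param noise_sd White-noise SD (default 0).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A list: `time_series`, `onsets` (the design), `truth` (named
#'   amplitude vector, tau, delay).
#' @export
generate_time_series <- function(design, n_volumes, amplitudes,
                                 tau = 1.2, delay = 1,
                                 localizer_amplitude = 0,
                                 localizer_cycles = 10,
                                 noise_sd = 0, seed = 1) {
  stopifnot(all(c("condition", "onset") %in% names(design)))
  conds <- unique(as.character(design$condition))
  if (!all(conds %in% names(amplitudes))) {
    stop("`amplitudes` must name every condition in `design`.", call. = FALSE)
  }
  ts <- numeric(n_volumes)
  t_idx <- seq_len(n_volumes)
  for (i in seq_len(nrow(design))) {
    on <- design$onset[i]
    amp <- amplitudes[[as.character(design$condition[i])]]
    ts <- ts + gamma_hrf(t_idx - on, amplitude = amp, tau = tau, delay = delay)
  }
  if (localizer_amplitude != 0) {
    ts <- ts + localizer_amplitude *
      sin(2 * pi * localizer_cycles * (t_idx - 1) / n_volumes)
  }
  if (noise_sd > 0) {
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    ts <- ts + stats::rnorm(n_volumes, 0, noise_sd)
  }
  list(time_series = ts, onsets = design,
       truth = list(amplitudes = amplitudes, tau = tau, delay = delay))
}

#' Write / read a synthetic voxel dataset as plain text
#'
#' Writes the voxel table as CSV together with a JSON ground-truth sidecar
#' (generating parameters and per-voxel expected attribute values) so every
#' dataset on disk is accompanied by what generated it.
#'
#' @param voxels A voxel table from [generate_voxels()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_voxels <- function(voxels, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("`jsonlite` is required to write the ground-truth sidecar.",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  voxel_path <- file.path(dir, "voxels.csv")
  truth_path <- file.path(dir, "voxels_truth.json")
  utils::write.csv(as.data.frame(voxels), voxel_path, row.names = FALSE)
  truth <- attr(voxels, "truth")
  payload <- list(
    params = truth$params[setdiff(names(truth$params), "")],
    per_voxel = truth$per_voxel
  )
  jsonlite::write_json(payload, truth_path, digits = NA, auto_unbox = TRUE)
  invisible(c(voxels = voxel_path, truth = truth_path))
}

#' @rdname write_voxels
#' @param path Path to a voxels CSV written by [write_voxels()].
#' @export
read_voxels <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}
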