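#' Coherence of a time series with the localizer stimulus frequency
#'
#' Coherence is the Fourier amplitude at the stimulus frequency divided by
#' the root sum of squared amplitudes over all nonzero frequencies (up to
#' the Nyquist frequency). It is 1 for a pure sinusoid at the stimulus
#' frequency and near 0 for signals with power elsewhere; it localizes
#' stimulus-responsive voxels in a cyclic localizer run.
#'
#' @param time_series Numeric vector, one value per volume.
#' @param stimulus_frequency Stimulus frequency in cycles per scan
#'   (positive integer, at least 2 cycles must fit in the series).
#' @return Coherence in `[0, 1]`.
#' @export
#' @examples
#' t <- seq_len(210)
#' compute_coherence(sin(2 * pi * 10 * (t - 1) / 210), 10)  # 1
compute_coherence <- function(time_series, stimulus_frequency) {
  n <- length(time_series)
  if (stimulus_frequency < 1 || stimulus_frequency != round(stimulus_frequency)) {
    stop("`stimulus_frequency` must be a positive integer number of cycles per scan.",
         call. = FALSE)
  }
  if (n < 2 * stimulus_frequency) {
    stop("Time series must contain at least 2 cycles of the stimulus frequency.",
         call. = FALSE)
  }
  amps <- Mod(stats::fft(time_series))
  nyq <- floor(n / 2)
  pos <- amps[seq(2, nyq + 1)]  # frequencies 1 .. Nyquist, DC excluded
  denom <- sqrt(sum(pos^2))
  # constant series leave only numerical dust at nonzero frequencies
  if (denom <= 1e-12 * (sum(abs(time_series)) + 1)) {
    stop("Time series has zero power at nonzero frequencies.", call. = FALSE)
  }
  pos[stimulus_frequency] / denom
}
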