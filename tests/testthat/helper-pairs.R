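# build an attended/unattended pair from the Naka-Rushton equation with one
# parameter changed in the attended condition
make_nr_pair <- function(r_max = 1, c50 = 20, n = 2, r_offset = 0,
                         free = c("r_offset", "c50", "r_max"),
                         attended_value = NULL,
                         contrasts = contrast_ladder(),
                         noise_sd = 0, seed = NULL) {
  free <- match.arg(free)
  pu <- list(r_max = r_max, c50 = c50, n = n, r_offset = r_offset)
  pa <- pu
  pa[[free]] <- attended_value %||% switch(free,
    r_max = 1.5 * r_max, c50 = 0.6 * c50, r_offset = r_offset + 0.15 * r_max)
  ru <- naka_rushton(contrasts, pu$r_max, pu$c50, pu$n, pu$r_offset)
  ra <- naka_rushton(contrasts, pa$r_max, pa$c50, pa$n, pa$r_offset)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ru <- ru + rnorm(length(ru), 0, noise_sd)
    ra <- ra + rnorm(length(ra), 0, noise_sd)
  }
  tibble::tibble(contrast = contrasts, r_unattended = ru, r_attended = ra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small grid for fast core-model tests
small_config <- function(...) {
  nma_config(space_extent = 5, space_step = 0.1, orientation_step = 15, ...)
}
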