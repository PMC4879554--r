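# Shared fixtures, all built in code.

# A plain spectrum on a uniform axis.
toy_spectrum <- function(n = 32, from = 700, step = 1,
                         intensities = seq_len(n), meta = list()) {
  raman_spectrum(seq(from, by = step, length.out = n), intensities, meta)
}

# A labelled set from an intensity matrix (rows = spectra) on a common axis;
# bypasses preprocessing for direct chemometrics tests.
set_from_matrix <- function(x, labels, from = 700, step = 1) {
  axis <- seq(from, by = step, length.out = ncol(x))
  spectra <- lapply(seq_len(nrow(x)), function(i)
    raman_spectrum(axis, x[i, ],
                   meta = list(spectrum_id = sprintf("s%03d", i),
                               group = labels[i])))
  raman_set(spectra, common_axis = axis)
}

# Two well-separated Gaussian clusters in channel space.
separated_toy_set <- function(n_per_group = 5, p = 24, shift = 6, seed = 42) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per_group * p), n_per_group),
    matrix(rnorm(n_per_group * p), n_per_group) +
      matrix(rep(c(rep(shift, 4), rep(0, p - 4)), each = n_per_group),
             n_per_group))
  set_from_matrix(x, rep(c("A", "B"), each = n_per_group))
}

# Unit-height Lorentzian profile.
lorentz <- function(wn, center, hwhm) hwhm^2 / ((wn - center)^2 + hwhm^2)
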