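# Preprocessing: the classification path (background subtraction ->
# Savitzky-Golay first derivative -> region interpolation -> vector
# normalization) and the mean-spectrum path (baseline correction, smoothing).

.regions <- list(
  fingerprint     = c(700, 1800),
  high_wavenumber = c(2800, 3100),
  tissue          = c(1200, 1800),
  full            = c(700, 3100)
)

#' Wavenumber bounds of a named spectral region
#' @param region `"fingerprint"` (700-1800 cm^-1), `"high_wavenumber"`
#'   (2800-3100), `"tissue"` (1200-1800) or `"full"` (700-3100); a numeric
#'   `c(lo, hi)` pair is passed through.
#' @return numeric length-2 vector in cm^-1.
#' @export
region_bounds <- function(region) {
  if (is.numeric(region) && length(region) == 2) return(sort(region))
  region <- match.arg(region, names(.regions))
  .regions[[region]]
}

#' Preprocessing configuration
#'
#' Defaults follow standard dispersive-Raman practice: 3-point first-order
#' Savitzky-Golay window, first derivative, 1 cm^-1 linear interpolation and
#' unit vector normalization for the classification path; fifth-order
#' polynomial baseline for the mean-spectrum path.
#'
#' @param sg_window odd integer >= 3, Savitzky-Golay window in points.
#' @param sg_polyorder polynomial order of the SG fit, < `sg_window`.
#' @param region region name or `c(lo, hi)` bounds, see [region_bounds()].
#' @param interp_step interpolation grid step in cm^-1, > 0.
#' @param baseline_poly_order baseline polynomial order (mean-spectrum path).
#' @param normalize `"vector"` (Euclidean norm 1) or `"none"`.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 3L, sg_polyorder = 1L,
                              region = "fingerprint", interp_step = 1,
                              baseline_poly_order = 5L,
                              normalize = c("vector", "none")) {
  sg_window <- as.integer(sg_window)
  if (sg_window < 3L || sg_window %% 2L == 0L)
    stop("sg_window must be an odd integer >= 3")
  if (sg_polyorder >= sg_window)
    stop("sg_polyorder must be smaller than sg_window")
  if (interp_step <= 0) stop("interp_step must be positive")
  structure(list(
    sg_window = sg_window, sg_polyorder = as.integer(sg_polyorder),
    region = region, interp_step = interp_step,
    baseline_poly_order = as.integer(baseline_poly_order),
    normalize = match.arg(normalize)
  ), class = "preprocess_config")
}

#' Subtract a background spectrum
#'
#' The background (substrate, fibre or instrument response signal) is linearly
#' interpolated onto the spectrum's axis and subtracted pointwise. Negative
#' results are allowed; the derivative path is shift and sign tolerant.
#'
#' @param spectrum,background [raman_spectrum] objects; the background must
#'   cover the spectrum's axis.
#' @return background-subtracted [raman_spectrum], metadata preserved.
#' @export
subtract_background <- function(spectrum, background) {
  wn <- spectrum$wavenumbers
  brange <- range(background$wavenumbers)
  if (wn[1] < brange[1] || wn[length(wn)] > brange[2])
    stop(sprintf(
      "background covers %.1f-%.1f cm^-1 but spectrum needs %.1f-%.1f",
      brange[1], brange[2], wn[1], wn[length(wn)]))
  bg <- stats::approx(background$wavenumbers, background$intensities,
                      xout = wn)$y
  out <- spectrum
  out$intensities <- spectrum$intensities - bg
  out
}

.check_uniform <- function(wn, what = "spectrum") {
  d <- diff(wn)
  if (diff(range(d)) > 1e-8 * mean(d))
    stop(what, " axis is not uniformly spaced; interpolate_region() first")
  mean(d)
}

.sg_apply <- function(spectrum, window, polyorder, deriv) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  if (window >= length(spectrum$wavenumbers))
    stop("window (", window, ") must be smaller than the spectrum length (",
         length(spectrum$wavenumbers), ")")
  step <- .check_uniform(spectrum$wavenumbers)
  out <- spectrum
  out$intensities <- as.numeric(signal::sgolayfilt(
    spectrum$intensities, p = polyorder, n = window, m = deriv, ts = step))
  out
}

#' Savitzky-Golay first derivative
#'
#' Removes slowly varying background by local polynomial differentiation.
#' Endpoints are handled by the filter's one-sided startup fits of the same
#' order, so a linear ramp differentiates exactly everywhere.
#'
#' @param spectrum a [raman_spectrum] on a uniform axis.
#' @param window odd integer >= 3 (points).
#' @param polyorder local polynomial order, default 1.
#' @return derivative [raman_spectrum] in intensity.cm units, same axis.
#' @export
sg_first_derivative <- function(spectrum, window = 3L, polyorder = 1L) {
  .sg_apply(spectrum, window, polyorder, deriv = 1L)
}

#' Savitzky-Golay smoothing
#'
#' Zero-order variant of [sg_first_derivative()]; preserves polynomials up to
#' `polyorder` exactly.
#'
#' @inheritParams sg_first_derivative
#' @return smoothed [raman_spectrum].
#' @export
sg_smooth <- function(spectrum, window = 3L, polyorder = 1L) {
  .sg_apply(spectrum, window, polyorder, deriv = 0L)
}

#' Interpolate a spectrum onto a uniform region grid
#'
#' Linear interpolation onto `seq(lo, hi, by = step)` for the requested
#' region; the region name is recorded in metadata.
#'
#' @param spectrum a [raman_spectrum] covering the region.
#' @param region region name or `c(lo, hi)`, see [region_bounds()].
#' @param step grid step in cm^-1.
#' @return interpolated [raman_spectrum] on the uniform grid.
#' @export
interpolate_region <- function(spectrum, region = "fingerprint", step = 1) {
  b <- region_bounds(region)
  supp <- range(spectrum$wavenumbers)
  if (b[1] < supp[1] || b[2] > supp[2])
    stop(sprintf(
      "region %.1f-%.1f cm^-1 outside spectrum support %.1f-%.1f",
      b[1], b[2], supp[1], supp[2]))
  grid <- seq(b[1], b[2], by = step)
  out <- spectrum
  out$wavenumbers <- grid
  out$intensities <- stats::approx(spectrum$wavenumbers, spectrum$intensities,
                                   xout = grid)$y
  out$meta$region <- if (is.character(region)) region else "custom"
  out
}

#' Vector (Euclidean) normalization
#'
#' @param spectrum a [raman_spectrum] with a non-zero intensity vector.
#' @return spectrum scaled to unit Euclidean norm.
#' @export
vector_normalize <- function(spectrum) {
  nrm <- sqrt(sum(spectrum$intensities^2))
  if (nrm == 0) stop("cannot vector-normalize an all-zero spectrum")
  out <- spectrum
  out$intensities <- spectrum$intensities / nrm
  out
}

#' Polynomial baseline correction
#'
#' Fits a least-squares polynomial of the given order over the whole axis and
#' subtracts it; the residual has zero projection onto the polynomial basis.
#' The fit is plain (no peak masking), as is conventional for fluorescence
#' background removal on mean spectra.
#'
#' @param spectrum a [raman_spectrum] with more than `poly_order + 1` points.
#' @param poly_order baseline polynomial order, default 5.
#' @return baseline-corrected [raman_spectrum].
#' @export
baseline_correct <- function(spectrum, poly_order = 5L) {
  n <- length(spectrum$wavenumbers)
  if (n <= poly_order + 1)
    stop("need more than poly_order + 1 = ", poly_order + 1, " points")
  x <- spectrum$wavenumbers
  fit <- stats::lm(spectrum$intensities ~ stats::poly(x, poly_order))
  out <- spectrum
  out$intensities <- as.numeric(stats::residuals(fit))
  out
}

#' Classification-path preprocessing for a whole set
#'
#' Per spectrum: optional background subtraction, Savitzky-Golay first
#' derivative, interpolation onto the region grid, vector normalization.
#' The operation order is fixed; the derivative precedes interpolation so
#' local slope information is computed on the native sampling.
#'
#' @param set a [raman_set] of raw spectra covering `cfg$region`.
#' @param cfg a [preprocess_config()].
#' @param background optional background [raman_spectrum] subtracted from
#'   every spectrum first.
#' @return a [raman_set] on the common region grid, every spectrum unit-norm
#'   (unless `cfg$normalize == "none"`).
#' @export
classification_pipeline <- function(set, cfg = preprocess_config(),
                                    background = NULL) {
  stopifnot(inherits(set, "raman_set"), inherits(cfg, "preprocess_config"))
  processed <- lapply(set$spectra, function(s) {
    id <- s$meta$spectrum_id %||% "<unnamed>"
    tryCatch({
      if (!is.null(background)) s <- subtract_background(s, background)
      d <- diff(s$wavenumbers)
      if (diff(range(d)) > 1e-8 * mean(d))
        s <- interpolate_region(s, range(s$wavenumbers), cfg$interp_step)
      s <- sg_first_derivative(s, cfg$sg_window, cfg$sg_polyorder)
      s <- interpolate_region(s, cfg$region, cfg$interp_step)
      if (cfg$normalize == "vector") s <- vector_normalize(s)
      s
    }, error = function(e)
      stop("preprocessing spectrum '", id, "': ", conditionMessage(e),
           call. = FALSE))
  })
  raman_set(processed, common_axis = processed[[1]]$wavenumbers)
}
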