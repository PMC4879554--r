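# Mean spectra per group, difference spectra, peak detection and band
# annotation -- the spectral-comparison path, run on non-derivatized data.

#' Group mean spectrum
#'
#' The spectral-comparison representation of one class: spectra are
#' (optionally) background-subtracted, interpolated onto the region grid and
#' averaged pointwise *before* any derivative; the average is then
#' baseline-corrected (polynomial), Savitzky-Golay smoothed and vector
#' normalized.
#'
#' @param set a [raman_set] of raw spectra.
#' @param group group label to average; must be non-empty in `set`.
#' @param cfg a [preprocess_config()]; `baseline_poly_order` and `sg_window`
#'   control the baseline and smoothing steps.
#' @param background optional background [raman_spectrum].
#' @return a [raman_spectrum] with metadata fields `group` and `n_averaged`.
#' @export
group_mean_spectrum <- function(set, group, cfg = preprocess_config(),
                                background = NULL) {
  idx <- which(set_labels(set) == group)
  if (!length(idx)) stop("no spectra in group '", group, "'")
  interp <- lapply(set$spectra[idx], function(s) {
    if (!is.null(background)) s <- subtract_background(s, background)
    interpolate_region(s, cfg$region, cfg$interp_step)
  })
  mean_int <- rowMeans(vapply(interp, function(s) s$intensities,
                              numeric(length(interp[[1]]$intensities))))
  avg <- raman_spectrum(interp[[1]]$wavenumbers, mean_int,
                        meta = list(group = group, n_averaged = length(idx),
                                    region = interp[[1]]$meta$region))
  avg <- baseline_correct(avg, cfg$baseline_poly_order)
  avg <- sg_smooth(avg, cfg$sg_window, cfg$sg_polyorder)
  avg <- vector_normalize(avg)
  avg$meta$group <- group
  avg$meta$n_averaged <- length(idx)
  avg
}

#' Difference spectrum between two mean spectra
#'
#' Signed pointwise subtraction `a - b` (convention: recurrent minus parent,
#' non-responder minus responder), so positive lobes mark biochemistry
#' enriched in `a`.
#'
#' @param a,b [raman_spectrum] objects on the same axis.
#' @return [raman_spectrum] of the difference; metadata records the operand
#'   order as `difference_of`.
#' @export
difference_spectrum <- function(a, b) {
  if (length(a$wavenumbers) != length(b$wavenumbers) ||
      any(a$wavenumbers != b$wavenumbers))
    stop("difference requires identical wavenumber axes")
  out <- a
  out$intensities <- a$intensities - b$intensities
  out$meta <- list(
    difference_of = paste0(a$meta$group %||% "a", " - ", b$meta$group %||% "b"),
    region = a$meta$region)
  out
}

# Prominence of each local maximum: height above the higher of the two
# minima separating it from the nearest taller point (or the record edge).
.peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p)]
    taller_l <- which(left > y[p])
    base_l <- min(left[seq(if (length(taller_l)) max(taller_l) else 1, p)])
    right <- y[p:length(y)]
    taller_r <- which(right > y[p])
    base_r <- min(right[seq(1, if (length(taller_r)) min(taller_r) else
      length(right))])
    y[p] - max(base_l, base_r)
  }, numeric(1))
}

.local_maxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

#' Detect peaks in a spectrum
#'
#' Local extrema of both signs whose prominence exceeds a threshold;
#' positions are reported at the grid resolution. Negative lobes (relevant
#' for difference spectra) are found by negating the signal.
#'
#' @param spectrum a [raman_spectrum].
#' @param min_prominence positive prominence threshold in intensity units;
#'   default 3 x the median absolute deviation of the intensities
#'   (scale-free).
#' @return data.frame with `position` (cm^-1), `height` (signed spectrum
#'   value at the extremum) and `sign` (+1 positive lobe, -1 negative),
#'   ordered by position.
#' @export
detect_peaks <- function(spectrum,
                         min_prominence = 3 * stats::mad(spectrum$intensities)) {
  if (!is.finite(min_prominence) || min_prominence <= 0)
    stop("min_prominence must be positive")
  y <- spectrum$intensities
  res <- list()
  for (sgn in c(1, -1)) {
    yy <- sgn * y
    pk <- .local_maxima(yy)
    pk <- pk[sgn * y[pk] > 0]  # a lobe's extremum carries the lobe's sign
    if (length(pk)) {
      prom <- .peak_prominences(yy, pk)
      keep <- prom >= min_prominence
      if (any(keep))
        res[[length(res) + 1]] <- data.frame(
          position = spectrum$wavenumbers[pk[keep]],
          height = y[pk[keep]], sign = sgn)
    }
  }
  if (!length(res))
    return(data.frame(position = numeric(0), height = numeric(0),
                      sign = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$position), , drop = FALSE]
}

#' Annotate detected peaks with biochemical band assignments
#'
#' Each peak is matched to every band whose window contains it
#' (`|center - position| <= window`); overlapping assignments such as
#' amide I and ceramide at 1660 cm^-1 are all reported. Unmatched peaks are
#' labelled `"unassigned"`.
#'
#' @param peaks data.frame from [detect_peaks()].
#' @param table band table, default [default_band_table()].
#' @return data.frame with one row per (peak, matching band): peak columns
#'   plus `band_center`, `assignment`, `class_association`.
#' @export
annotate_bands <- function(peaks, table = default_band_table()) {
  if (!nrow(peaks))
    return(cbind(peaks, band_center = numeric(0), assignment = character(0),
                 class_association = character(0)))
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    hit <- which(abs(table$center - peaks$position[i]) <= table$window)
    if (!length(hit))
      return(cbind(peaks[i, , drop = FALSE], band_center = NA_real_,
                   assignment = "unassigned",
                   class_association = NA_character_))
    cbind(peaks[i, , drop = FALSE][rep(1, length(hit)), , drop = FALSE],
          band_center = table$center[hit],
          assignment = table$assignment[hit],
          class_association = table$class_association[hit])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Integrated band area in a wavenumber window
#'
#' Trapezoidal integral of the intensity over `[lo, hi]`; used to quantify
#' broad features such as the 2840-2880 cm^-1 lipid CH2 envelope whose
#' breadth, not just height, separates classes.
#'
#' @param spectrum a [raman_spectrum] covering the window.
#' @param lo,hi window bounds in cm^-1.
#' @return scalar area (intensity x cm^-1).
#' @export
band_area <- function(spectrum, lo, hi) {
  keep <- spectrum$wavenumbers >= lo & spectrum$wavenumbers <= hi
  if (sum(keep) < 2) stop("window contains fewer than 2 points")
  x <- spectrum$wavenumbers[keep]
  y <- spectrum$intensities[keep]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
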