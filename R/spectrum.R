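#' Construct a Raman spectrum
#'
#' A spectrum is one acquisition: a strictly increasing wavenumber axis
#' (cm^-1), matching intensities (arbitrary units) and provenance metadata.
#'
#' @param wavenumbers numeric, Raman shift in cm^-1; strictly increasing after
#'   sorting, all finite and positive, length >= 8.
#' @param intensities numeric, same length as `wavenumbers`, all finite.
#'   Negative values are allowed (derivative spectra are signed).
#' @param meta named list of provenance fields; recognised keys are
#'   `spectrum_id`, `sample_id`, `group`, `batch` and `region` (one of
#'   `"fingerprint"`, `"high_wavenumber"`, `"tissue"`, `"full"`).
#'
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have the same length")
  if (length(wavenumbers) < 8L)
    stop("a spectrum needs at least 8 points, got ", length(wavenumbers))
  if (!all(is.finite(wavenumbers)) || any(wavenumbers <= 0))
    stop("wavenumbers must all be finite and positive")
  if (!all(is.finite(intensities)))
    stop("intensities must all be finite")
  ord <- order(wavenumbers)
  wavenumbers <- wavenumbers[ord]
  intensities <- intensities[ord]
  if (any(diff(wavenumbers) == 0))
    stop("duplicate wavenumbers are not allowed")
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         meta = as.list(meta)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), rng[1], rng[2]))
  keys <- c("spectrum_id", "sample_id", "group", "batch", "region")
  keys <- keys[keys %in% names(x$meta)]
  if (length(keys))
    cat("  ", paste(sprintf("%s=%s", keys, unlist(x$meta[keys])),
                    collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumbers, intensity = x$intensities)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumbers)

is_raman_spectrum <- function(x) inherits(x, "raman_spectrum")

#' Construct a labelled spectrum collection
#'
#' A `raman_set` is the unit of training and validation: a list of spectra
#' carrying group labels, optionally sharing a common wavenumber axis (set by
#' the preprocessing pipeline).
#'
#' @param spectra list of [raman_spectrum] objects, each with a non-empty
#'   `group` metadata field.
#' @param common_axis optional numeric axis every spectrum must match exactly.
#'
#' @return An object of class `raman_set` with elements `spectra`,
#'   `common_axis` and `groups` (sorted unique labels).
#' @export
raman_set <- function(spectra, common_axis = NULL) {
  if (!length(spectra) || !all(vapply(spectra, is_raman_spectrum, logical(1))))
    stop("spectra must be a non-empty list of raman_spectrum objects")
  groups <- vapply(spectra, function(s) {
    g <- s$meta$group
    if (is.null(g) || !nzchar(g)) stop("every spectrum needs a group label")
    as.character(g)
  }, character(1))
  if (!is.null(common_axis)) {
    common_axis <- as.numeric(common_axis)
    ok <- vapply(spectra, function(s)
      length(s$wavenumbers) == length(common_axis) &&
        all(s$wavenumbers == common_axis), logical(1))
    if (!all(ok))
      stop("spectra ", paste(which(!ok), collapse = ", "),
           " do not match the common axis")
  }
  structure(
    list(spectra = spectra, common_axis = common_axis,
         groups = sort(unique(groups))),
    class = "raman_set"
  )
}

#' @export
print.raman_set <- function(x, ...) {
  tab <- table(set_labels(x))
  cat(sprintf("<raman_set> %d spectra, %d groups%s\n", length(x$spectra),
              length(x$groups),
              if (is.null(x$common_axis)) "" else
                sprintf(", common axis of %d points", length(x$common_axis))))
  print(tab)
  invisible(x)
}

#' @export
length.raman_set <- function(x) length(x$spectra)

#' Group label of every spectrum in a set
#' @param set a [raman_set].
#' @return character vector, one label per spectrum.
#' @export
set_labels <- function(set) {
  vapply(set$spectra, function(s) as.character(s$meta$group), character(1))
}

#' Intensity matrix of a set on its common axis
#'
#' @param set a [raman_set] whose `common_axis` is set (run
#'   [classification_pipeline()] first for raw data).
#' @return numeric matrix, spectra in rows, wavenumbers in columns (named by
#'   axis value); row names are spectrum ids where present.
#' @export
set_matrix <- function(set) {
  if (is.null(set$common_axis))
    stop("set has no common axis; preprocess it first")
  m <- do.call(rbind, lapply(set$spectra, function(s) s$intensities))
  colnames(m) <- format(set$common_axis, trim = TRUE)
  ids <- vapply(set$spectra, function(s)
    if (is.null(s$meta$spectrum_id)) NA_character_ else
      as.character(s$meta$spectrum_id), character(1))
  if (!anyNA(ids)) rownames(m) <- ids
  m
}

#' Subset a raman_set by spectrum index
#' @param set a [raman_set].
#' @param i integer or logical index over spectra.
#' @return a [raman_set] with the selected spectra (common axis kept).
#' @export
set_subset <- function(set, i) {
  raman_set(set$spectra[i], common_axis = set$common_axis)
}
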