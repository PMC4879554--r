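# Plain-text spectrum and manifest I/O.
#
# Spectrum files are two numeric columns "wavenumber intensity" (whitespace or
# comma delimited), with optional '#' comment lines; '#key: value' comments
# are parsed into metadata. Manifests are CSV with the header
# path,spectrum_id,sample_id,group,batch.

#' Read a spectrum from a two-column text file
#'
#' @param path path to a delimited text file; comma or whitespace delimiter is
#'   auto-detected. Lines starting with `#` are comments; `#key: value`
#'   comments populate the spectrum metadata.
#' @return A [raman_spectrum] sorted by ascending wavenumber.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("cannot read spectrum file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  is_comment <- startsWith(trimws(lines), "#")
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(data_idx)) stop("no data rows in ", path)
  wn <- numeric(length(data_idx))
  it <- numeric(length(data_idx))
  for (k in seq_along(data_idx)) {
    ln <- trimws(lines[data_idx[k]])
    fields <- strsplit(ln, "[,[:space:]]+")[[1]]
    fields <- fields[nzchar(fields)]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || anyNA(vals[1:2]))
      stop("parse error in ", path, " at line ", data_idx[k], ": '", ln, "'")
    wn[k] <- vals[1]; it[k] <- vals[2]
  }
  if (anyDuplicated(wn))
    stop("duplicate wavenumber in ", path, ": ",
         paste(unique(wn[duplicated(wn)]), collapse = ", "))
  raman_spectrum(wn, it, meta)
}

#' Write a spectrum to a two-column text file
#'
#' Metadata is stored as `#key: value` header comments so that
#' `read_spectrum(write_spectrum(s, f))` reproduces the spectrum, values at
#' full double precision.
#'
#' @param spectrum a [raman_spectrum].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(is_raman_spectrum(spectrum))
  hdr <- character(0)
  for (key in names(spectrum$meta)) {
    val <- spectrum$meta[[key]]
    if (length(val) == 1 && !is.null(val))
      hdr <- c(hdr, sprintf("#%s: %s", key, as.character(val)))
  }
  rows <- sprintf("%.17g %.17g", spectrum$wavenumbers, spectrum$intensities)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a manifest table
#'
#' @param path CSV file with the header `path,spectrum_id,sample_id,group,batch`.
#'   Relative spectrum paths are resolved against the manifest's directory.
#' @return data.frame with those five character columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  required <- c("path", "spectrum_id", "sample_id", "group", "batch")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  if (!nrow(df)) stop("manifest is empty")
  if (anyDuplicated(df$spectrum_id))
    stop("duplicate spectrum_id in manifest: ",
         paste(unique(df$spectrum_id[duplicated(df$spectrum_id)]), collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df[required]
}

#' Load a labelled spectrum set from a manifest
#'
#' Each manifest row is loaded with [read_spectrum()]; the manifest's id,
#' sample, group and batch fields override any header metadata in the files.
#'
#' @param manifest data.frame as returned by [read_manifest()], or a path to
#'   a manifest CSV.
#' @return A [raman_set]; no common axis is imposed (preprocessing aligns).
#' @export
load_set <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1)
    manifest <- read_manifest(manifest)
  if (!nrow(manifest)) stop("manifest is empty")
  missing <- !file.exists(manifest$path)
  if (any(missing))
    stop("missing spectrum file(s): ",
         paste(manifest$path[missing], collapse = ", "))
  spectra <- lapply(seq_len(nrow(manifest)), function(i) {
    s <- read_spectrum(manifest$path[i])
    s$meta$spectrum_id <- manifest$spectrum_id[i]
    s$meta$sample_id <- manifest$sample_id[i]
    s$meta$group <- manifest$group[i]
    s$meta$batch <- manifest$batch[i]
    s
  })
  raman_set(spectra)
}

#' Write a spectrum set plus manifest to a directory
#'
#' @param set a [raman_set]; every spectrum needs `spectrum_id`, `sample_id`,
#'   `group` and `batch` metadata.
#' @param dir output directory, created if absent; spectra are written as
#'   `<spectrum_id>.txt` and indexed by `manifest.csv`.
#' @return Path to the manifest, invisibly.
#' @export
write_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(set$spectra, function(s) {
    id <- s$meta$spectrum_id
    if (is.null(id)) stop("spectrum without spectrum_id cannot be exported")
    fn <- paste0(id, ".txt")
    write_spectrum(s, file.path(dir, fn))
    data.frame(path = fn, spectrum_id = id,
               sample_id = as.character(s$meta$sample_id %||% id),
               group = as.character(s$meta$group),
               batch = as.character(s$meta$batch %||% "b1"))
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
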