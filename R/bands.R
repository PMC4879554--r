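# Biochemical band assignments used for annotation and simulation.

#' Default Raman band assignment table
#'
#' Fingerprint- and high-wavenumber-region bands of cellular biochemistry
#' (proteins, nucleic acids, lipids) with their conventional assignments and
#' the class whose spectra are enriched at each band in the
#' glioblastoma parent/recurrent and tissue responder/non-responder
#' comparisons the package targets.
#'
#' @param window half-width of the matching window in cm^-1 applied to every
#'   band, default 8 (covers reported intra-band drift such as 1447 vs 1450
#'   without cross-band confusion).
#' @return data.frame with columns `center` (cm^-1), `window` (+- cm^-1),
#'   `assignment`, `class_association` (one of `parent`, `recurrent`,
#'   `non_responder`, `responder`, `shared`).
#' @export
default_band_table <- function(window = 8) {
  b <- function(center, assignment, assoc) {
    data.frame(center = center, window = window, assignment = assignment,
               class_association = assoc)
  }
  rbind(
    b(1008, "phenylalanine ring breathing", "parent"),
    b(1095, "DNA backbone (PO2- symmetric stretch)", "parent"),
    b(1260, "amide III", "shared"),
    b(1262, "amide III (beta)", "recurrent"),
    b(1272, "lipid =CH bend / amide III", "recurrent"),
    b(1305, "lipid CH2 twist", "recurrent"),
    b(1313, "CH3/CH2 twisting of lipid/collagen", "non_responder"),
    b(1320, "DNA bases / amide III (alpha-helix) / lipid CH2 deformation",
      "non_responder"),
    b(1340, "total nucleic acid content", "parent"),
    b(1367, "phospholipid", "non_responder"),
    b(1447, "CH2 bending (lipid-shifted)", "recurrent"),
    b(1450, "CH2 bending (protein)", "parent"),
    b(1485, "G and A bases of DNA", "non_responder"),
    b(1560, "tryptophan", "parent"),
    b(1579, "DNA and heme", "non_responder"),
    b(1610, "cytosine base", "parent"),
    b(1660, "amide I / ceramide backbone", "recurrent"),
    b(1673, "ceramide shoulder", "recurrent"),
    b(1725, "lipid C=O stretch", "recurrent"),
    b(1746, "lipid C=O ester stretch", "recurrent"),
    b(1750, "lipid C=O ester (tissue)", "non_responder"),
    b(2850, "lipid CH2 symmetric stretch", "recurrent"),
    b(2880, "lipid CH2 asymmetric stretch", "recurrent"),
    b(2900, "protein CH3 stretch", "parent"),
    b(2930, "protein CH3 symmetric stretch", "parent")
  )
}

#' Read a band table from CSV
#' @param path CSV with columns `center,window,assignment,class_association`.
#' @return band table data.frame as in [default_band_table()].
#' @export
read_band_table <- function(path) {
  df <- utils::read.csv(path)
  required <- c("center", "window", "assignment", "class_association")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("band table is missing columns: ", paste(missing, collapse = ", "))
  if (any(df$center <= 0) || any(df$window <= 0))
    stop("band centers and windows must be positive")
  df[required]
}
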