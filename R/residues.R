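#' @keywords internal
"_PACKAGE"

## Six physico-chemical residue categories used for all pair attributes.
## The partition is fixed: hydrophobic ILVM, aromatic FYW, small AGSTCP,
## polar NQ, positive HKR, negative DE.
.category_members <- list(
  hydrophobic = c("I", "L", "V", "M"),
  aromatic    = c("F", "Y", "W"),
  small       = c("A", "G", "S", "T", "C", "P"),
  polar       = c("N", "Q"),
  positive    = c("H", "K", "R"),
  negative    = c("D", "E")
)

#' Residue category names, in canonical order
#'
#' Order used throughout for the per-category attribute blocks:
#' hydrophobic, aromatic, small, polar, positive, negative.
#' @return character vector of length 6
#' @export
residue_categories <- function() names(.category_members)

#' The 20 standard amino-acid one-letter codes, alphabetical
#' @return character vector of length 20
#' @export
residue_types <- function() sort(unlist(.category_members, use.names = FALSE))

#' Map a residue type to its physico-chemical category
#'
#' Total function from the 20 standard one-letter codes onto the six
#' categories (hydrophobic ILVM, aromatic FYW, small AGSTCP, polar NQ,
#' positive HKR, negative DE).
#'
#' @param residue_type character vector of one-letter codes
#' @return character vector of category names
#' @examples
#' category_of(c("L", "W", "D"))
#' @export
category_of <- function(residue_type) {
  lut <- rep(names(.category_members), lengths(.category_members))
  names(lut) <- unlist(.category_members, use.names = FALSE)
  bad <- !(residue_type %in% names(lut))
  if (any(bad)) {
    stop("unknown residue: ", paste(unique(residue_type[bad]), collapse = ", "))
  }
  unname(lut[residue_type])
}

.aa321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.aa123 <- structure(names(.aa321), names = unname(.aa321))

#' Mean residue volumes
#'
#' Loads the per-residue mean volume table (one-letter code -> mean volume
#' in cubic Angstroms). The default table shipped with the package holds the
#' Pontius et al. (1996) Voronoi mean residue volumes; the file is plain TSV
#' and can be replaced to use another volume set.
#'
#' @param path path to a two-column TSV (columns \code{residue}, \code{volume}).
#'   Defaults to the packaged table.
#' @return named numeric vector of length 20, names are one-letter codes
#' @export
volume_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "residue_volumes.tsv", package = "voroscore")
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  v <- structure(as.numeric(tab$volume), names = tab$residue)
  missing <- setdiff(residue_types(), names(v))
  if (length(missing) > 0)
    stop("volume table incomplete, missing: ", paste(missing, collapse = ", "))
  if (any(!is.finite(v)) || any(v <= 0))
    stop("volume table must contain positive finite volumes")
  v[residue_types()]
}
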