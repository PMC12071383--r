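#' Standard amino-acid three-letter codes
#'
#' The 20 standard amino acids in alphabetical order of their three-letter
#' codes (upper case, PDB convention).
#'
#' @return Character vector of length 20.
#' @export
standard_aa <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

#' Amino-acid residue volumes
#'
#' Residue volumes in cubic Angstrom used for wild-type/mutant volume
#' ratios.  The default set is Zamyatnin's classical residue volumes
#' (e.g. Gly 60.1, Val 140.0, Trp 227.8).  Any other table can be supplied
#' through [load_volume_table()] or by editing the returned vector; all
#' downstream code takes the table as an argument.
#'
#' @param set Name of the built-in set; currently only `"zamyatnin"`.
#' @return Named numeric vector (names = three-letter codes, values in A^3).
#' @seealso [volume_ratio()], [load_volume_table()]
#' @export
aa_volumes <- function(set = "zamyatnin") {
  set <- match.arg(set)
  c(ALA =  88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1, CYS = 108.5,
    GLN = 143.8, GLU = 138.4, GLY =  60.1, HIS = 153.2, ILE = 166.7,
    LEU = 166.7, LYS = 168.6, MET = 162.9, PHE = 189.9, PRO = 112.7,
    SER =  89.0, THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)
}

#' Read a residue-volume table from file
#'
#' Expects a TSV or CSV file with columns `residue` (three-letter code) and
#' `volume` (A^3).  All 20 standard residues must be present with positive
#' volumes, and Gly must be the smallest (a basic sanity check on the
#' physical meaning of the table).
#'
#' @param path Path to the table.
#' @return Named numeric vector as in [aa_volumes()].
#' @export
load_volume_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("residue", "volume") %in% names(df)))
    stop("volume table must have columns 'residue' and 'volume': ", path)
  v <- df$volume
  names(v) <- toupper(df$residue)
  missing <- setdiff(standard_aa(), names(v))
  if (length(missing))
    stop("volume table is missing residues: ", paste(missing, collapse = ", "))
  v <- v[standard_aa()]
  if (any(!is.finite(v)) || any(v <= 0))
    stop("volume table contains non-positive or non-finite volumes")
  if (names(v)[which.min(v)] != "GLY")
    stop("implausible volume table: Gly is not the smallest residue")
  v
}

#' Van der Waals radii by element
#'
#' Bondi-type heavy-atom radii (A) used to build the protein body.
#' Elements not listed fall back to the carbon value of 1.70 A.
#'
#' @return Named numeric vector with an attribute `default` holding the
#'   fallback radius.
#' @export
default_vdw_radii <- function() {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90, P = 1.80)
  attr(r, "default") <- 1.70
  r
}

#' Read a van der Waals radii table from file
#'
#' TSV/CSV with columns `element` and `radius` (A).  The fallback radius for
#' unlisted elements is the carbon entry if present, 1.70 A otherwise.
#'
#' @param path Path to the table.
#' @return Named numeric vector as in [default_vdw_radii()].
#' @export
load_radii_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("element", "radius") %in% names(df)))
    stop("radii table must have columns 'element' and 'radius': ", path)
  r <- df$radius
  names(r) <- toupper(df$element)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("radii table contains non-positive or non-finite radii")
  attr(r, "default") <- if ("C" %in% names(r)) unname(r[["C"]]) else 1.70
  r
}

# Radius lookup for a vector of element symbols.
vdw_lookup <- function(element, radii = default_vdw_radii()) {
  out <- unname(radii[toupper(element)])
  out[is.na(out)] <- attr(radii, "default") %||% 1.70
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backbone atom names; everything else among heavy atoms is side chain.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
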