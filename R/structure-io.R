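#' Parse a PDB-format structure
#'
#' Reads ATOM records (wwPDB v3.3 fixed columns) into the internal
#' heavy-atom model.  Hydrogens, HETATM records (waters, ligands) and
#' everything after the first model are excluded; for alternate locations
#' only the highest-occupancy conformer is kept (ties: first encountered).
#' Elements are taken from columns 77-78 when present and otherwise derived
#' from the atom name.  Each atom is assigned a van der Waals radius from
#' the configured element table.
#'
#' Only a single chain is retained (the monomeric view of the analysis):
#' the first chain encountered by default, or the chain requested via
#' `chain`.
#'
#' @param text PDB text: a character vector of lines or a single string.
#' @param id Structure identifier stored on the object.
#' @param chain Chain identifier to keep; `NULL` keeps the first chain.
#' @param source `"experimental"` or `"predicted"` (AlphaFold-style model
#'   whose B-factor column holds pLDDT).
#' @param on_nonstandard What to do with non-standard residues
#'   (`"skip"` with a warning, or `"error"`).
#' @param radii Van der Waals radii table, see [default_vdw_radii()].
#' @return A `protein_structure`: list with `id`, `atoms` (data frame with
#'   serial, name, altloc, resname, chain, resseq, icode, x, y, z,
#'   occupancy, bfactor, element, vdw) and `source`.
#' @export
parse_structure <- function(text, id = "structure", chain = NULL,
                            source = c("experimental", "predicted"),
                            on_nonstandard = c("skip", "error"),
                            radii = default_vdw_radii()) {
  source <- match.arg(source)
  on_nonstandard <- match.arg(on_nonstandard)
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text

  # first model only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines_use <- seq_len(endmdl[1] - 1L)
  else lines_use <- seq_along(lines)

  is_atom <- startsWith(lines, "ATOM") & seq_along(lines) %in% lines_use
  idx <- which(is_atom)
  if (!length(idx)) stop("no ATOM records found in PDB input")

  ln <- sprintf("%-80s", lines[idx])
  fld <- function(a, b) substr(ln, a, b)
  num <- function(a, b, what) {
    s <- trimws(fld(a, b))
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & s != "")
    if (length(bad))
      stop(sprintf("malformed %s field in ATOM record at line %d: '%s'",
                   what, idx[bad[1]], trimws(lines[idx[bad[1]]])))
    v
  }

  at <- data.frame(
    serial  = num(7, 11, "serial"),
    name    = trimws(fld(13, 16)),
    altloc  = fld(17, 17),
    resname = toupper(trimws(fld(18, 20))),
    chain   = trimws(fld(22, 22)),
    resseq  = num(23, 26, "residue number"),
    icode   = fld(27, 27),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    occupancy = num(55, 60, "occupancy"),
    bfactor   = num(61, 66, "B-factor"),
    element   = toupper(trimws(fld(77, 78))),
    stringsAsFactors = FALSE
  )
  at$line <- idx
  bad_xyz <- which(is.na(at$x) | is.na(at$y) | is.na(at$z))
  if (length(bad_xyz))
    stop(sprintf("missing coordinate field in ATOM record at line %d",
                 at$line[bad_xyz[1]]))
  at$occupancy[is.na(at$occupancy)] <- 1
  at$bfactor[is.na(at$bfactor)] <- 0

  # element fallback from the atom name (digits stripped, first letter)
  need <- at$element == ""
  if (any(need)) {
    nm <- gsub("[^A-Za-z]", "", at$name[need])
    at$element[need] <- toupper(substr(nm, 1, 1))
  }
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at)) stop("no heavy atoms left after excluding hydrogens")

  # chain selection: first chain encountered unless requested
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records for chain '", chain, "'")

  nonstd <- !(at$resname %in% standard_aa())
  if (any(nonstd)) {
    what <- paste(unique(at$resname[nonstd]), collapse = ", ")
    if (on_nonstandard == "error")
      stop("non-standard residues present: ", what)
    warning("skipping non-standard residues: ", what)
    at <- at[!nonstd, , drop = FALSE]
  }
  if (!nrow(at)) stop("no standard-residue atoms left after filtering")

  # alternate locations: highest occupancy wins, ties -> first encountered
  key <- paste(at$chain, at$resseq, at$icode, at$resname, at$name, sep = "|")
  if (anyDuplicated(key)) {
    ord <- order(key, -at$occupancy, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(at$line), , drop = FALSE]
  }

  if (!any(at$name == "CA"))
    stop("structure has no residue with a CA atom")

  at$vdw <- vdw_lookup(at$element, radii)
  at$line <- NULL
  rownames(at) <- NULL
  structure(list(id = id, atoms = at, source = source),
            class = "protein_structure")
}

#' Read a PDB file from disk
#'
#' Thin wrapper around [parse_structure()].  The source is auto-detected as
#' `"predicted"` when the header mentions AlphaFold, and can always be
#' forced through `source`.
#'
#' @param path Path to a PDB file.
#' @param id Structure id; defaults to the file name without extension.
#' @param source `"auto"`, `"experimental"` or `"predicted"`.
#' @param ... Passed on to [parse_structure()].
#' @return A `protein_structure`.
#' @export
read_structure <- function(path, id = NULL, source = "auto", ...) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (identical(source, "auto")) {
    head50 <- toupper(paste(utils::head(lines, 50), collapse = " "))
    source <- if (grepl("ALPHAFOLD", head50)) "predicted" else "experimental"
  }
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path),
                             ignore.case = TRUE)
  parse_structure(lines, id = id, source = source, ...)
}

#' @export
print.protein_structure <- function(x, ...) {
  rk <- residue_keys(x)
  cat(sprintf("<protein_structure '%s'> %d heavy atoms, %d residues, chain %s, %s\n",
              x$id, nrow(x$atoms), length(rk), x$atoms$chain[1], x$source))
  invisible(x)
}

# Unique residue keys "chain|resseq|icode" in order of appearance.
residue_keys <- function(structure) {
  at <- structure$atoms
  unique(paste(at$chain, at$resseq, at$icode, sep = "|"))
}

# Row indices of a residue's atoms in structure$atoms.
residue_rows <- function(structure, chain, resseq, icode = " ") {
  at <- structure$atoms
  which(at$chain == chain & at$resseq == resseq &
          (at$icode == icode | (trimws(icode) == "" & trimws(at$icode) == "")))
}

#' Write a depth-annotated PDB stream
#'
#' Emits valid PDB ATOM records for the structure with the per-atom depth
#' index written in the B-factor column (2 decimals), mirroring
#' depth-annotated structure files.  Round-tripping through
#' [parse_structure()] recovers identical coordinates.
#'
#' @param structure A `protein_structure`.
#' @param depths Named numeric vector of depth indices (names = atom
#'   serials), e.g. from [compute_atom_depths()].  Every atom must have one.
#' @param file Optional path; when given the records are written there.
#' @return Character vector of PDB lines, invisibly when `file` is given.
#' @export
write_depth_annotated <- function(structure, depths, file = NULL) {
  at <- structure$atoms
  d <- depths[as.character(at$serial)]
  if (any(is.na(d))) {
    miss <- at$serial[is.na(d)]
    stop("missing depth value for atom serial(s): ",
         paste(miss, collapse = ", "))
  }
  name4 <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
                  sprintf(" %-3s", at$name))
  rec <- sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 at$serial, name4, at$altloc, at$resname, at$chain,
                 at$resseq, at$icode, at$x, at$y, at$z, at$occupancy, d,
                 at$element)
  out <- c(rec, "TER", "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Per-residue pLDDT confidence from a predicted model
#'
#' AlphaFold-style models store the per-residue pLDDT score in the B-factor
#' column.  The per-residue confidence is the mean B-factor over the
#' residue's atoms; files on the 0-100 scale (detected by any B-factor
#' above 1.5) are rescaled to 0-1.
#'
#' @param structure A `protein_structure` with `source == "predicted"`.
#' @return Data frame with chain, resseq, icode, resname and plddt (0-1).
#' @export
extract_plddt <- function(structure) {
  if (structure$source != "predicted")
    stop("pLDDT extraction requires a predicted-model structure")
  at <- structure$atoms
  if (any(at$bfactor < 0))
    stop("negative B-factor encountered; not a valid pLDDT column")
  key <- paste(at$chain, at$resseq, at$icode, sep = "|")
  keys <- unique(key)
  m <- vapply(keys, function(k) mean(at$bfactor[key == k]), numeric(1))
  if (any(at$bfactor > 1.5)) m <- m / 100
  first <- match(keys, key)
  data.frame(chain = at$chain[first], resseq = at$resseq[first],
             icode = at$icode[first], resname = at$resname[first],
             plddt = unname(m), stringsAsFactors = FALSE)
}
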