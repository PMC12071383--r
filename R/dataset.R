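#' Parse missense mutation notation
#'
#' Parses strings of the form `Aaa<N>Bbb` ("Val149Gly"): wild-type residue,
#' 1-based sequence position, mutant residue.  Three-letter codes are
#' validated case-insensitively against the 20 standard amino acids.
#'
#' @param s Character vector of mutation strings.
#' @return Data frame with `wild_aa`, `position`, `mutant_aa` (codes upper
#'   case).
#' @export
parse_mutation_notation <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", s))
  bad <- which(vapply(m, length, integer(1)) != 4L)
  if (length(bad))
    stop("malformed mutation notation: '", s[bad[1]],
         "' (expected e.g. Val149Gly)")
  wild <- toupper(vapply(m, `[[`, character(1), 2))
  pos <- as.integer(vapply(m, `[[`, character(1), 3))
  mut <- toupper(vapply(m, `[[`, character(1), 4))
  unknown <- setdiff(unique(c(wild, mut)), standard_aa())
  if (length(unknown))
    stop("unknown residue code in mutation notation: ",
         paste(unknown, collapse = ", "))
  if (any(pos < 1L))
    stop("mutation position must be a positive integer: '",
         s[which(pos < 1L)[1]], "'")
  data.frame(wild_aa = wild, position = pos, mutant_aa = mut,
             stringsAsFactors = FALSE)
}

#' Read a variant table
#'
#' Tab-separated file with header columns `gene`, `uniprot`, `mutation`
#' (Aaa\code{<N>}Bbb notation), `structure` (file stem of the PDB file),
#' and optional `chain` and `offset` (author numbering = position +
#' offset).
#'
#' @param path Path to the TSV file.
#' @return Data frame with the columns above (`chain` defaulting to `NA`,
#'   `offset` to 0).
#' @export
read_variant_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "")
  need <- c("gene", "uniprot", "mutation", "structure")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"chain" %in% names(df)) df$chain <- NA_character_
  if (!"offset" %in% names(df)) df$offset <- 0L
  df$offset[is.na(df$offset)] <- 0L
  df
}

#' Locate a mutation site in a structure
#'
#' Looks up the residue at author numbering `position + offset` and checks
#' that its residue name equals the expected wild type.  The identity check
#' is strict: a mismatch is reported, never silently profiled.
#'
#' @param structure A `protein_structure` (already restricted to one chain).
#' @param wild_aa Expected wild-type three-letter code.
#' @param position Sequence position of the mutation.
#' @param offset Numbering offset (author resseq = position + offset).
#' @return List with `status` (`"ok"`, `"missing_residue"`, or
#'   `"residue_mismatch"`), `resseq` (the author number looked up) and
#'   `found` (residue name found, or `NA`).
#' @export
map_site_to_structure <- function(structure, wild_aa, position, offset = 0) {
  resseq <- position + offset
  ch <- structure$atoms$chain[1]
  rows <- residue_rows(structure, ch, resseq)
  if (!length(rows))
    return(list(status = "missing_residue", resseq = resseq,
                found = NA_character_))
  found <- structure$atoms$resname[rows[1]]
  if (found != toupper(wild_aa))
    return(list(status = "residue_mismatch", resseq = resseq, found = found))
  list(status = "ok", resseq = resseq, found = found)
}

#' pLDDT confidence filter for predicted models
#'
#' Experimental structures pass automatically.  A predicted model passes
#' for a given site when the mean per-residue pLDDT over the chain exceeds
#' the threshold AND the site residue's pLDDT exceeds it (both strictly).
#'
#' @param structure A `protein_structure`.
#' @param resseq Author residue number of the site.
#' @param threshold Confidence threshold on the 0-1 scale (default 0.8).
#' @param plddt Optional precomputed [extract_plddt()] table.
#' @return `TRUE` when the site passes.
#' @export
apply_plddt_filter <- function(structure, resseq, threshold = 0.8,
                               plddt = NULL) {
  if (structure$source != "predicted") return(TRUE)
  if (is.null(plddt)) plddt <- extract_plddt(structure)
  site <- plddt$plddt[plddt$resseq == resseq]
  if (!length(site)) return(FALSE)
  mean(plddt$plddt) > threshold && site[1] > threshold
}

#' Profile a set of missense mutation sites
#'
#' Runs the whole per-site pipeline: structure lookup, wild-type identity
#' check, pLDDT filtering, atom depth computation (one voxel grid per
#' structure, cached), residue depth summary, orientation, cluster
#' assignment, volume ratio and pocket-candidate flag.  Output rows are in
#' input order, one per record; rows that cannot be profiled carry a
#' status naming the reason and the run continues.
#'
#' @param variants Data frame as from [read_variant_table()].
#' @param structures Either a named list of `protein_structure` objects
#'   (names matching the `structure` column) or a directory containing
#'   `<structure>.pdb` files.
#' @param params [depth_params()] for the depth computation.
#' @param cfg [classifier_config()] for the cluster assignment.
#' @param volumes Residue-volume table, see [aa_volumes()].
#' @param plddt_min pLDDT threshold for predicted models.
#' @return Data frame (`profile_table`) with gene, uniprot, mutation,
#'   wild_aa, position, mutant_aa, cluster, orientation, d_alpha, d_sc,
#'   ratio, v_ratio, pocket_candidate, status.
#' @export
profile_variants <- function(variants, structures,
                             params = depth_params(),
                             cfg = classifier_config(),
                             volumes = aa_volumes(),
                             plddt_min = 0.8) {
  n <- nrow(variants)
  out <- data.frame(
    gene = character(n), uniprot = character(n), mutation = character(n),
    wild_aa = character(n), position = integer(n), mutant_aa = character(n),
    cluster = rep(NA_integer_, n), orientation = rep(NA_character_, n),
    d_alpha = rep(NA_real_, n), d_sc = rep(NA_real_, n),
    ratio = rep(NA_real_, n), v_ratio = rep(NA_real_, n),
    pocket_candidate = rep(NA, n), status = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  if (!n) {
    class(out) <- c("profile_table", "data.frame")
    return(out)
  }
  out$gene <- variants$gene
  out$uniprot <- variants$uniprot
  out$mutation <- variants$mutation
  parsed <- parse_mutation_notation(variants$mutation)
  out$wild_aa <- parsed$wild_aa
  out$position <- parsed$position
  out$mutant_aa <- parsed$mutant_aa
  chain <- if ("chain" %in% names(variants)) variants$chain
           else rep(NA_character_, n)
  offset <- if ("offset" %in% names(variants)) {
    o <- variants$offset; o[is.na(o)] <- 0L; o
  } else rep(0L, n)

  from_dir <- !is.list(structures) || inherits(structures, "protein_structure")
  if (inherits(structures, "protein_structure"))
    stop("'structures' must be a *named list* of structures or a directory")
  get_structure <- function(name, ch) {
    if (!from_dir) {
      s <- structures[[name]]
      if (is.null(s)) return(NULL)
      return(s)
    }
    path <- file.path(structures, paste0(name, ".pdb"))
    if (!file.exists(path)) return(NULL)
    tryCatch(read_structure(path, chain = if (is.na(ch)) NULL else ch),
             error = function(e) NULL)
  }

  skey <- paste(variants$structure, ifelse(is.na(chain), "", chain))
  for (k in unique(skey)) {
    rows <- which(skey == k)
    s <- get_structure(variants$structure[rows[1]], chain[rows[1]])
    if (is.null(s)) {
      out$status[rows] <- "missing_structure"
      next
    }
    plddt <- if (s$source == "predicted") extract_plddt(s) else NULL
    # map every site first, so depth is computed once for the union of sites
    maps <- lapply(rows, function(i)
      map_site_to_structure(s, out$wild_aa[i], out$position[i], offset[i]))
    ok <- vapply(maps, function(m) m$status == "ok", logical(1))
    for (j in which(!ok)) out$status[rows[j]] <- maps[[j]]$status
    pass <- ok
    if (!is.null(plddt)) {
      for (j in which(ok)) {
        if (!apply_plddt_filter(s, maps[[j]]$resseq, plddt_min, plddt)) {
          out$status[rows[j]] <- "plddt_filtered"
          pass[j] <- FALSE
        }
      }
    }
    if (!any(pass)) next
    ch0 <- s$atoms$chain[1]
    serials <- unlist(lapply(which(pass), function(j)
      s$atoms$serial[residue_rows(s, ch0, maps[[j]]$resseq)]))
    grid <- voxelize(s, params)
    depths <- compute_atom_depths(s, params, grid = grid,
                                  serials = unique(serials))
    for (j in which(pass)) {
      i <- rows[j]
      rd <- residue_depth_profile(s, depths, ch0, maps[[j]]$resseq)
      cl <- assign_cluster(out$wild_aa[i], rd$d_alpha, rd$d_sc, cfg)
      vr <- volume_ratio(out$wild_aa[i], out$mutant_aa[i], volumes)
      out$cluster[i] <- cl
      out$orientation[i] <- classify_orientation(rd$d_alpha, rd$d_sc)
      out$d_alpha[i] <- rd$d_alpha
      out$d_sc[i] <- rd$d_sc
      out$ratio[i] <- rd$ratio
      out$v_ratio[i] <- vr
      out$pocket_candidate[i] <- flag_pocket_candidate(cl, vr, cfg)
      out$status[i] <- "profiled"
    }
  }
  class(out) <- c("profile_table", "data.frame")
  out
}

#' Write a profile table as TSV
#'
#' Fixed column order and formatting (depths to 3 decimals, ratios to 2),
#' no timestamps: identical inputs give byte-identical output.
#'
#' @param profile A `profile_table` from [profile_variants()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  fmt <- function(x, d) ifelse(is.na(x), "NA", formatC(x, digits = d,
                                                       format = "f"))
  df <- data.frame(
    gene = profile$gene, uniprot = profile$uniprot,
    mutation = profile$mutation,
    cluster = ifelse(is.na(profile$cluster), "NA", profile$cluster),
    orientation = ifelse(is.na(profile$orientation), "NA",
                         profile$orientation),
    D_ia = fmt(profile$d_alpha, 3), D_isc = fmt(profile$d_sc, 3),
    ratio = fmt(profile$ratio, 2), v_ratio = fmt(profile$v_ratio, 2),
    pocket_candidate = ifelse(is.na(profile$pocket_candidate), "NA",
                              ifelse(profile$pocket_candidate, "true",
                                     "false")),
    status = profile$status, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile TSV back into a profile table
#'
#' Inverse of [write_profile_tsv()] (numeric precision limited to what was
#' printed).  Used by the `summarize` command.
#'
#' @param path Path to a profile TSV.
#' @return A `profile_table` data frame.
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  parsed <- parse_mutation_notation(df$mutation)
  out <- data.frame(
    gene = df$gene, uniprot = df$uniprot, mutation = df$mutation,
    wild_aa = parsed$wild_aa, position = parsed$position,
    mutant_aa = parsed$mutant_aa, cluster = as.integer(df$cluster),
    orientation = df$orientation, d_alpha = df$D_ia, d_sc = df$D_isc,
    ratio = df$ratio, v_ratio = df$v_ratio,
    pocket_candidate = df$pocket_candidate == "true",
    status = df$status, stringsAsFactors = FALSE)
  out$pocket_candidate[is.na(df$pocket_candidate)] <- NA
  class(out) <- c("profile_table", "data.frame")
  out
}
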