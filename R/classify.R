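#' Classifier configuration
#'
#' Thresholds and amino-acid sets of the three-cluster topological
#' classification of mutation sites:
#'
#' * Cluster 1 (inner layer): `d_alpha <= inner_depth_max`, side chain
#'   pointing inward (`d_sc < d_alpha`), wild-type residue among the small
#'   or hydrophobic `inner_aa_set`.
#' * Cluster 2 (outer layer): `d_sc > outer_depth_min`, side chain pointing
#'   outward (`d_sc > d_alpha`), wild-type residue among the bulky or
#'   charged `outer_aa_set`.
#' * Cluster 3 (intermediate): every other case.
#'
#' Substitutions in cluster 2 that replace the wild type by a residue
#' smaller by more than `volume_ratio_min` (V/v strictly greater) are
#' flagged as surface-pocket candidates.
#'
#' @param inner_depth_max Upper bound (inclusive) on `d_alpha` for cluster 1.
#' @param outer_depth_min Lower bound (strict) on `d_sc` for cluster 2.
#' @param volume_ratio_min Strict lower bound on V/v for pocket candidates.
#' @param inner_aa_set,outer_aa_set Three-letter codes of eligible wild
#'   types for clusters 1 and 2.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(inner_depth_max = 0.2,
                              outer_depth_min = 0.5,
                              volume_ratio_min = 1.3,
                              inner_aa_set = c("ALA", "CYS", "GLY", "ILE",
                                               "LEU", "MET", "PHE", "VAL"),
                              outer_aa_set = c("TYR", "PHE", "LEU", "ILE",
                                               "VAL", "TRP", "MET", "ASP",
                                               "GLU", "HIS", "LYS", "ARG")) {
  inner_aa_set <- toupper(inner_aa_set)
  outer_aa_set <- toupper(outer_aa_set)
  if (inner_depth_max >= outer_depth_min)
    stop("inner_depth_max must be below outer_depth_min")
  bad <- setdiff(c(inner_aa_set, outer_aa_set), standard_aa())
  if (length(bad))
    stop("non-standard residues in amino-acid sets: ",
         paste(bad, collapse = ", "))
  structure(list(inner_depth_max = inner_depth_max,
                 outer_depth_min = outer_depth_min,
                 volume_ratio_min = volume_ratio_min,
                 inner_aa_set = inner_aa_set,
                 outer_aa_set = outer_aa_set),
            class = "classifier_config")
}

#' Side-chain orientation from a depth summary
#'
#' A side chain is oriented toward the protein surface (`"outward"`) when
#' the mean side-chain depth exceeds the C-alpha depth strictly; ties and
#' the reverse ordering give `"inward"`.
#'
#' @param d_alpha,d_sc C-alpha and mean side-chain depth indices
#'   (vectorized).
#' @return Character vector, `"outward"` or `"inward"`.
#' @export
classify_orientation <- function(d_alpha, d_sc) {
  ifelse(d_sc > d_alpha, "outward", "inward")
}

#' Assign a mutation site to a topological cluster
#'
#' Applies the three-cluster rule (see [classifier_config()]) to the
#' wild-type residue and its depth summary.  Glycine carries the
#' `d_sc = d_alpha` convention, under which the strict inward inequality of
#' cluster 1 can never hold; since Gly is explicitly part of the inner-layer
#' amino-acid set, Gly sites are assigned cluster 1 whenever
#' `d_alpha <= inner_depth_max` (and cluster 3 otherwise).
#'
#' @param wild_aa Wild-type three-letter code(s).
#' @param d_alpha,d_sc Depth summary of the site (vectorized).
#' @param cfg A [classifier_config()].
#' @return Integer vector of cluster labels in `{1, 2, 3}`.
#' @export
assign_cluster <- function(wild_aa, d_alpha, d_sc,
                           cfg = classifier_config()) {
  wild_aa <- toupper(wild_aa)
  bad <- setdiff(unique(wild_aa), standard_aa())
  if (length(bad))
    stop("non-standard wild-type residue code: ", paste(bad, collapse = ", "))
  n <- max(length(wild_aa), length(d_alpha), length(d_sc))
  wild_aa <- rep_len(wild_aa, n)
  d_alpha <- rep_len(d_alpha, n)
  d_sc <- rep_len(d_sc, n)
  gly <- wild_aa == "GLY"
  d_sc[gly] <- d_alpha[gly]  # enforce the Gly convention on input
  c1 <- d_alpha <= cfg$inner_depth_max &
    ifelse(gly, TRUE, d_sc < d_alpha) &
    wild_aa %in% cfg$inner_aa_set
  c2 <- !c1 & d_sc > cfg$outer_depth_min & d_sc > d_alpha &
    wild_aa %in% cfg$outer_aa_set
  out <- rep(3L, n)
  out[c2] <- 2L
  out[c1] <- 1L
  out
}

#' Wild-type to mutant residue volume ratio
#'
#' `V/v` where `V` is the volume of the wild-type residue and `v` the
#' volume of the mutant, from a residue-volume table.  The ratio depends
#' only on the amino-acid pair, never on the structure.
#'
#' @param wild_aa,mutant_aa Three-letter codes (vectorized).
#' @param volumes Named volume table, see [aa_volumes()].
#' @return Numeric vector of ratios (full precision; round to 2 decimals
#'   for display).
#' @export
volume_ratio <- function(wild_aa, mutant_aa, volumes = aa_volumes()) {
  wild_aa <- toupper(wild_aa)
  mutant_aa <- toupper(mutant_aa)
  bad <- setdiff(unique(c(wild_aa, mutant_aa)), names(volumes))
  if (length(bad))
    stop("residue(s) missing from the volume table: ",
         paste(bad, collapse = ", "))
  unname(volumes[wild_aa] / volumes[mutant_aa])
}

#' Flag surface-pocket candidate substitutions
#'
#' A site is a pocket candidate when it belongs to cluster 2 (outer layer,
#' outward side chain) and the substitution removes enough bulk:
#' `v_ratio > volume_ratio_min` (strict).
#'
#' @param cluster Integer cluster labels.
#' @param v_ratio V/v volume ratios.
#' @param cfg A [classifier_config()].
#' @return Logical vector.
#' @export
flag_pocket_candidate <- function(cluster, v_ratio,
                                  cfg = classifier_config()) {
  cluster == 2L & v_ratio > cfg$volume_ratio_min
}
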