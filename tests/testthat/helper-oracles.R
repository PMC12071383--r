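# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive expected values by different means than the
# package code paths they check.

# --- PDB text construction -------------------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          occ = 1, b = 0, element = "", altloc = " ",
                          record = "ATOM") {
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %-2s",
          record, serial, name4, altloc, resname, chain, resseq, " ",
          x, y, z, occ, b, element)
}

# Canonical heavy-atom name sets (PDB nomenclature).
IDEAL_ATOMS <- list(
  GLY = c("N", "CA", "C", "O"),
  ALA = c("N", "CA", "C", "O", "CB"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
          "CE3", "CZ2", "CZ3", "CH2"))

# A fabricated PDB text with one residue per entry of `residues`
# (list of list(resseq, resname)); residues are strung along x, atoms
# slightly offset so coordinates are distinct.
synth_pdb <- function(residues, chain = "A", b = 0) {
  lines <- character(0)
  serial <- 0L
  for (k in seq_along(residues)) {
    rs <- residues[[k]]
    names_k <- IDEAL_ATOMS[[rs$resname]]
    if (is.null(names_k)) names_k <- c("N", "CA", "C", "O", "CB")
    bk <- if (length(b) > 1) b[k] else b
    for (j in seq_along(names_k)) {
      serial <- serial + 1L
      el <- substr(gsub("[0-9]", "", names_k[j]), 1, 1)
      lines <- c(lines, pdb_atom_line(
        serial, names_k[j], rs$resname, chain, rs$resseq,
        x = 4 * k + 0.5 * j, y = 0.3 * j, z = 0.2 * k, b = bk,
        element = el))
    }
  }
  lines
}

# --- Monte-Carlo depth oracle ---------------------------------------------

# Depth by uniform sampling in the reference sphere with a point-in-union
# occupancy test (same body definition as the voxel engine with cavity
# filling disabled).  Returns the estimate and its standard error.
mc_depth <- function(s, serial, r = 10, nsamp = 1e5, seed = 7) {
  set.seed(seed)
  at <- s$atoms
  ctr <- unlist(at[at$serial == serial, c("x", "y", "z")])
  u <- matrix(stats::rnorm(3 * nsamp), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- r * stats::runif(nsamp)^(1 / 3)
  pts <- sweep(u * rad, 2, ctr, "+")
  occ <- rep(FALSE, nsamp)
  for (i in seq_len(nrow(at))) {
    d2 <- (pts[, 1] - at$x[i])^2 + (pts[, 2] - at$y[i])^2 +
      (pts[, 3] - at$z[i])^2
    occ <- occ | (d2 <= at$vdw[i]^2)
  }
  f <- mean(!occ)
  list(depth = 2 * f, se = 2 * sqrt(f * (1 - f) / nsamp))
}

# A reproducible random atom cluster (no internal cavities of consequence).
random_blob <- function(n = 30, sd = 3, seed = 42) {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n, sd = sd), ncol = 3)
  sitedepth:::new_structure(xyz[, 1], xyz[, 2], xyz[, 3], id = "blob")
}

# --- Brute-force cluster rule ----------------------------------------------

# Scalar re-coding of the three-cluster rule, straight from its textual
# definition, kept independent of the vectorized implementation.
oracle_cluster <- function(aa, da, dsc) {
  inner <- c("ALA", "CYS", "GLY", "ILE", "LEU", "MET", "PHE", "VAL")
  outer <- c("TYR", "PHE", "LEU", "ILE", "VAL", "TRP", "MET", "ASP",
             "GLU", "HIS", "LYS", "ARG")
  if (aa == "GLY") {
    # glycine convention: d_sc equals d_alpha, inward inequality relaxed
    if (da <= 0.2) return(1L)
    return(3L)
  }
  if (da <= 0.2 && dsc < da && aa %in% inner) return(1L)
  if (dsc > 0.5 && dsc > da && aa %in% outer) return(2L)
  3L
}

# --- Array-shift flood fill -------------------------------------------------

# Boundary-connected free voxels by iterated face-neighbor dilation
# (different mechanics than the package's BFS).
shift_flood <- function(free) {
  d <- dim(free)
  reach <- array(FALSE, d)
  reach[1, , ] <- free[1, , ]; reach[d[1], , ] <- free[d[1], , ]
  reach[, 1, ] <- reach[, 1, ] | free[, 1, ]
  reach[, d[2], ] <- reach[, d[2], ] | free[, d[2], ]
  reach[, , 1] <- reach[, , 1] | free[, , 1]
  reach[, , d[3]] <- reach[, , d[3]] | free[, , d[3]]
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
    grown <- grown & free
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}
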