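# Constructors for synthetic structures: geometric bodies with analytic
# expected depths, and a helix bundle with planted side-chain orientations.
# All generators are deterministic under their seed.

# Cubic-lattice interior plus a Fibonacci shell at radius - vdw, so the
# body (union of vdW spheres) is a solid ball whose surface sits at the
# nominal radius in every direction, not at the lattice quantization.
solid_ball_points <- function(radius, spacing, vdw) {
  reach <- radius - vdw
  if (reach < 0) stop("radius must exceed the vdW radius")
  g <- seq(-floor(reach / spacing), floor(reach / spacing)) * spacing
  pts <- expand.grid(x = g, y = g, z = g)
  pts <- pts[sqrt(pts$x^2 + pts$y^2 + pts$z^2) <= reach, , drop = FALSE]
  if (reach > 0) {
    n <- max(32L, ceiling(4 * pi * reach^2 / spacing^2))
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    shell <- data.frame(x = reach * sin(phi) * cos(theta),
                        y = reach * sin(phi) * sin(theta),
                        z = reach * cos(phi))
    pts <- rbind(pts, shell)
  }
  pts
}

# Assemble a protein_structure from coordinate/metadata vectors.
new_structure <- function(x, y, z, name = "CA", element = "C",
                          resname = "GLY", resseq = seq_along(x),
                          chain = "A", bfactor = 90, id = "synthetic",
                          source = "predicted",
                          radii = default_vdw_radii()) {
  n <- length(x)
  at <- data.frame(
    serial = seq_len(n), name = rep_len(name, n),
    altloc = rep_len(" ", n), resname = rep_len(resname, n),
    chain = rep_len(chain, n), resseq = rep_len(resseq, n),
    icode = rep_len(" ", n), x = x, y = y, z = z,
    occupancy = rep_len(1, n), bfactor = rep_len(bfactor, n),
    element = rep_len(element, n), stringsAsFactors = FALSE)
  at$vdw <- vdw_lookup(at$element, radii)
  structure(list(id = id, atoms = at, source = source),
            class = "protein_structure")
}

#' Analytic depth of an atom inside a solid ball
#'
#' Closed-form expected depth index for an atom at distance `a` from the
#' center of a solid spherical body of radius `R`, with reference radius
#' `r`: twice the fraction of the reference sphere outside the body
#' (two-sphere intersection volume).  Serves as the independent oracle for
#' the lattice-ball fixtures.
#'
#' @param a Distance of the atom from the body center (A).
#' @param R Body radius (A).
#' @param r Reference-sphere radius (A).
#' @return Expected depth index in `[0, 2]`.
#' @export
analytic_ball_depth <- function(a, R, r) {
  v_sphere <- 4 / 3 * pi * r^3
  if (a + r <= R) return(0)
  if (a >= R + r) return(2)
  if (a < 1e-12) return(2 * max(0, 1 - (R / r)^3))
  d <- a
  v_int <- pi * (R + r - d)^2 *
    (d^2 + 2 * d * r - 3 * r^2 + 2 * d * R + 6 * r * R - 3 * R^2) / (12 * d)
  2 * (1 - v_int / v_sphere)
}

#' Geometric depth fixtures with analytic expected values
#'
#' Builds a pseudo-protein of carbon atoms (one single-atom residue per
#' lattice point, vdW 1.70 A) whose expected depth at a reference atom is
#' known in closed form:
#'
#' * `single_atom`: one atom; expected `D = 2 (1 - (vdw/r)^3)` (~1.990 at
#'   r = 10).
#' * `lattice_ball`: cubic lattice filling a solid ball; `radius` is the
#'   radius of the *body* (atom centers reach `radius - vdw`); expected
#'   center-atom depth `2 (1 - (radius/r)^3)` for `radius < r`, 0 when the
#'   reference sphere is fully enclosed.
#' * `slab`: lattice half-space whose body surface is the z = 0 plane,
#'   plus a face atom at the origin; expected face-atom depth
#'   `2 (1/2 - (vdw/r)^3 / 2)` (~1.0, half-space symmetry).
#' * `shell_with_cavity`: Fibonacci-lattice spherical shell of atoms
#'   enclosing an empty cavity of radius `shell_radius - vdw`; used to
#'   exercise cavity filling (no analytic depth attached).
#'
#' @param kind One of `"single_atom"`, `"lattice_ball"`, `"slab"`,
#'   `"shell_with_cavity"`.
#' @param radius Body radius for `lattice_ball` (A).
#' @param spacing Lattice spacing (A); values above twice the vdW radius
#'   cannot produce a solid body and trigger a warning.
#' @param half_extent Lateral half-extent of the slab (A).
#' @param thickness Depth of the slab body below its surface (A).
#' @param shell_radius Radius of the shell atom centers (A).
#' @param reference_radius Reference radius the expected values are quoted
#'   for (A).
#' @param plddt Value planted in the B-factor column.
#' @param seed Unused (generators are deterministic); kept so all fixture
#'   constructors share one signature.
#' @return List with `structure`, `target_serial` (the atom the expected
#'   value refers to; `NA` for the shell), `expected_depth`, and
#'   `cavity_center`/`cavity_radius` for the shell fixture.
#' @export
make_geometric_fixture <- function(kind = c("single_atom", "lattice_ball",
                                            "slab", "shell_with_cavity"),
                                   radius = 5, spacing = 1,
                                   half_extent = 25, thickness = 10,
                                   shell_radius = 3.7,
                                   reference_radius = 10,
                                   plddt = 90, seed = 1) {
  kind <- match.arg(kind)
  vdw <- unname(default_vdw_radii()[["C"]])
  if (spacing <= 0) stop("spacing must be positive")
  if (kind %in% c("lattice_ball", "slab") && spacing > 2 * vdw)
    warning("spacing exceeds twice the vdW radius; the body will not be solid")
  r <- reference_radius
  if (kind == "single_atom") {
    s <- new_structure(0, 0, 0, bfactor = plddt, id = "single_atom")
    return(list(structure = s, target_serial = 1L,
                expected_depth = 2 * (1 - (vdw / r)^3)))
  }
  if (kind == "lattice_ball") {
    pts <- solid_ball_points(radius, spacing, vdw)
    # put the center atom first so it is serial 1
    ord <- order(pts$x^2 + pts$y^2 + pts$z^2)
    pts <- pts[ord, , drop = FALSE]
    s <- new_structure(pts$x, pts$y, pts$z, bfactor = plddt,
                       id = "lattice_ball")
    return(list(structure = s, target_serial = 1L,
                expected_depth = analytic_ball_depth(0, radius, r)))
  }
  if (kind == "slab") {
    gx <- seq(-half_extent, half_extent, by = spacing)
    gz <- seq(-vdw, -vdw - thickness, by = -spacing)
    pts <- expand.grid(x = gx, y = gx, z = gz)
    xyz <- rbind(c(0, 0, 0), as.matrix(pts))  # face atom first
    s <- new_structure(xyz[, 1], xyz[, 2], xyz[, 3], bfactor = plddt,
                       id = "slab")
    return(list(structure = s, target_serial = 1L,
                expected_depth = 2 * (0.5 - 0.5 * (vdw / r)^3)))
  }
  # shell_with_cavity: Fibonacci sphere, angular spacing ~ `spacing`
  n <- max(32L, ceiling(4 * pi * shell_radius^2 / spacing^2))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  xyz <- shell_radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                              cos(phi))
  s <- new_structure(xyz[, 1], xyz[, 2], xyz[, 3], bfactor = plddt,
                     id = "shell_with_cavity")
  list(structure = s, target_serial = NA_integer_,
       expected_depth = NA_real_,
       cavity_center = c(0, 0, 0), cavity_radius = shell_radius - vdw)
}

#' Idealized helix bundle with planted side-chain orientations
#'
#' Builds `n_helices` parallel idealized alpha-helices (rise 1.5 A, 100
#' degrees per residue, C-alpha helix radius 2.3 A) arranged on a circle of
#' radius `bundle_radius`.  Each residue carries an approximate backbone
#' (N, CA, C, O) and a single CB pseudo-atom placed along the bundle-radial
#' direction through its CA: away from the bundle axis for residues whose
#' CA faces the outside (label `"outward"`), toward the axis for residues
#' facing the core (label `"inward"`).  The labels are the ground truth the
#' depth pipeline is expected to recover.  All residues are named ALA and
#' numbered consecutively across helices in one chain.
#'
#' @param n_helices Number of helices (>= 3 so an interior exists).
#' @param n_res Residues per helix.
#' @param seed Integer seed for the per-helix phase offsets.
#' @param bundle_radius Distance of each helix axis from the bundle axis (A).
#' @param cb_length CB displacement from CA (A).
#' @param plddt Value planted in the B-factor column.
#' @return List with `structure` and `labels` (data frame: resseq, helix,
#'   index within helix, facing cosine, label).
#' @export
make_helix_bundle <- function(n_helices = 4, n_res = 20, seed = 1,
                              bundle_radius = 6.5, cb_length = 1.8,
                              plddt = 90) {
  if (n_helices < 3) stop("n_helices must be >= 3 so an interior exists")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  phase0 <- stats::runif(n_helices, 0, 2 * pi)

  rise <- 1.5; turn <- 100 * pi / 180; r_ca <- 2.3
  rows <- vector("list", n_helices * n_res)
  lab <- vector("list", n_helices * n_res)
  resseq <- 0L
  for (m in seq_len(n_helices)) {
    ang <- 2 * pi * (m - 1) / n_helices
    axis <- bundle_radius * c(cos(ang), sin(ang))
    for (t in seq_len(n_res)) {
      resseq <- resseq + 1L
      th <- phase0[m] + (t - 1) * turn
      zc <- (t - 1) * rise
      ca <- c(axis + r_ca * c(cos(th), sin(th)), zc)
      nn <- c(axis + 1.6 * c(cos(th - 0.58), sin(th - 0.58)), zc - 0.6)
      cc <- c(axis + 1.7 * c(cos(th + 0.58), sin(th + 0.58)), zc + 0.6)
      oo <- c(axis + 2.1 * c(cos(th + 0.70), sin(th + 0.70)), zc + 1.7)
      helix_rad <- c(cos(th), sin(th))              # CA direction off helix axis
      bundle_rad <- ca[1:2] / sqrt(sum(ca[1:2]^2))  # radial through CA
      facing <- sum(helix_rad * c(cos(ang), sin(ang)))
      outward <- facing >= 0
      cb <- ca + cb_length * c(if (outward) bundle_rad else -bundle_rad, 0)
      xyz <- rbind(nn, ca, cc, oo, cb)
      rows[[resseq]] <- data.frame(
        name = c("N", "CA", "C", "O", "CB"),
        element = c("N", "C", "C", "O", "C"),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        resseq = resseq, stringsAsFactors = FALSE)
      lab[[resseq]] <- data.frame(
        resseq = resseq, helix = m, index = t, facing = facing,
        label = if (outward) "outward" else "inward",
        stringsAsFactors = FALSE)
    }
  }
  at <- do.call(rbind, rows)
  s <- new_structure(at$x, at$y, at$z, name = at$name, element = at$element,
                     resname = "ALA", resseq = at$resseq, bfactor = plddt,
                     id = "helix_bundle")
  list(structure = s, labels = do.call(rbind, lab))
}

#' Lattice-ball pseudo-protein with a planted buried residue
#'
#' A solid lattice ball (body radius `ball_radius`) with one full residue
#' embedded on the +x axis: CA at radial distance `ca_radial`, CB displaced
#' `cb_length` further toward the center (inward orientation), N/C/O
#' nearby.  The expected depths of CA and CB follow the analytic solid-ball
#' oracle ([analytic_ball_depth()]), so cluster-1 ground truth (small
#' wild-type residue, `d_alpha` at or below the inner threshold, side chain
#' strictly deeper) holds by construction with `ball_radius = 12`,
#' `ca_radial = 3.5` and `r = 10`.
#'
#' @param ball_radius Body radius (A).
#' @param spacing Filler lattice spacing (A).
#' @param ca_radial Radial position of the planted CA (A).
#' @param cb_length CB displacement toward the center (A).
#' @param resname Residue name of the planted site.
#' @param site_resseq Residue number given to the planted site.
#' @param plddt Value planted in the B-factor column.
#' @param reference_radius Reference radius for the expected values (A).
#' @param seed Unused; uniform generator signature.
#' @return List with `structure`, `site` (resseq, resname, expected
#'   `d_alpha`/`d_sc` from the analytic oracle).
#' @export
make_buried_site_fixture <- function(ball_radius = 12, spacing = 1,
                                     ca_radial = 3.5, cb_length = 1.8,
                                     resname = "ALA", site_resseq = 9000L,
                                     plddt = 90, reference_radius = 10,
                                     seed = 1) {
  vdw <- unname(default_vdw_radii()[["C"]])
  pts <- solid_ball_points(ball_radius, spacing, vdw)
  filler_n <- nrow(pts)
  ca <- c(ca_radial, 0, 0)
  cb <- c(ca_radial - cb_length, 0, 0)
  nn <- ca + c(0.8, 1.2, 0); cc <- ca + c(0.8, -1.2, 0)
  oo <- ca + c(1.9, -1.6, 0)
  at <- data.frame(
    name = c(rep("CA", filler_n), "N", "CA", "C", "O", "CB"),
    element = c(rep("C", filler_n), "N", "C", "C", "O", "C"),
    x = c(pts$x, nn[1], ca[1], cc[1], oo[1], cb[1]),
    y = c(pts$y, nn[2], ca[2], cc[2], oo[2], cb[2]),
    z = c(pts$z, nn[3], ca[3], cc[3], oo[3], cb[3]),
    resname = c(rep("GLY", filler_n), rep(resname, 5)),
    resseq = c(seq_len(filler_n), rep(site_resseq, 5)),
    stringsAsFactors = FALSE)
  s <- new_structure(at$x, at$y, at$z, name = at$name, element = at$element,
                     resname = at$resname, resseq = at$resseq,
                     bfactor = plddt, id = "buried_ball")
  r <- reference_radius
  list(structure = s,
       site = list(resseq = site_resseq, resname = resname,
                   expected_d_alpha = analytic_ball_depth(ca_radial,
                                                          ball_radius, r),
                   expected_d_sc = analytic_ball_depth(ca_radial - cb_length,
                                                       ball_radius, r)))
}

# Rename a residue in place (and optionally drop its CB), used to plant
# wild-type identities on fixture sites.
rename_residue <- function(structure, resseq, resname, drop_cb = FALSE) {
  at <- structure$atoms
  sel <- at$resseq == resseq
  if (!any(sel)) stop("no residue ", resseq, " in fixture")
  at$resname[sel] <- resname
  if (drop_cb) at <- at[!(sel & at$name == "CB"), , drop = FALSE]
  structure$atoms <- at
  structure
}

#' Variant table with ground-truth cluster assignments
#'
#' Plants mutation sites on synthetic structures so the expected profile is
#' known by construction:
#'
#' * cluster-2 pocket candidates: robustly outward-facing surface residues
#'   of a helix bundle renamed to Trp, mutated to Gly (V/v well above 1.3);
#' * cluster-2 non-candidates: outward Lys sites mutated to Arg (V/v below
#'   1);
#' * cluster-3 sites: inward-facing bundle residues renamed to Ser (Ser
#'   belongs to neither amino-acid set, so the label is depth-independent)
#'   mutated to Ala;
#' * an optional surface Gly site (exercises the Gly convention; expected
#'   cluster 3 because a surface `d_alpha` is far above the inner
#'   threshold);
#' * an optional cluster-1 site: the planted buried Ala of
#'   [make_buried_site_fixture()] mutated to Val.
#'
#' "Robust" bundle sites have |facing cosine| >= 0.5 and sit away from the
#' helix ends, so the planted orientation survives the depth pipeline.
#'
#' @param bundle Output of [make_helix_bundle()]; built with `seed` when
#'   `NULL`.
#' @param seed Seed forwarded to the generators.
#' @param n_pocket,n_nonpocket,n_inward Numbers of planted sites per class.
#' @param include_gly,include_buried Include the Gly-convention site and
#'   the buried cluster-1 structure.
#' @return List with `structures` (named list), `variants` (data frame:
#'   gene, uniprot, mutation, structure, chain, offset) and `expected`
#'   (mutation, structure, cluster, orientation, pocket_candidate, status).
#' @export
make_variant_fixture <- function(bundle = NULL, seed = 1, n_pocket = 3,
                                 n_nonpocket = 2, n_inward = 3,
                                 include_gly = TRUE, include_buried = TRUE) {
  if (is.null(bundle)) bundle <- make_helix_bundle(seed = seed)
  s <- bundle$structure
  lab <- bundle$labels
  n_res_per_helix <- max(lab$index)
  robust <- lab$index >= 4 & lab$index <= n_res_per_helix - 3 &
    abs(lab$facing) >= 0.5
  out_sites <- lab$resseq[robust & lab$label == "outward"]
  in_sites <- lab$resseq[robust & lab$label == "inward"]
  need_out <- n_pocket + n_nonpocket + as.integer(include_gly)
  if (length(out_sites) < need_out || length(in_sites) < n_inward)
    stop("bundle too small for the requested number of planted sites")

  pocket <- out_sites[seq_len(n_pocket)]
  nonpocket <- out_sites[n_pocket + seq_len(n_nonpocket)]
  gly_site <- if (include_gly) out_sites[n_pocket + n_nonpocket + 1L]
              else integer(0)
  inward <- in_sites[seq_len(n_inward)]

  for (rs in pocket) s <- rename_residue(s, rs, "TRP")
  for (rs in nonpocket) s <- rename_residue(s, rs, "LYS")
  for (rs in inward) s <- rename_residue(s, rs, "SER")
  for (rs in gly_site) s <- rename_residue(s, rs, "GLY", drop_cb = TRUE)
  bundle$structure <- s

  mk <- function(resseq, wild, mut, structure_id) {
    data.frame(mutation = sprintf("%s%d%s",
                                  paste0(substr(wild, 1, 1),
                                         tolower(substr(wild, 2, 3))),
                                  resseq,
                                  paste0(substr(mut, 1, 1),
                                         tolower(substr(mut, 2, 3)))),
               structure = structure_id, stringsAsFactors = FALSE)
  }
  v <- rbind(
    do.call(rbind, lapply(pocket, mk, wild = "TRP", mut = "GLY",
                          structure_id = "bundle")),
    do.call(rbind, lapply(nonpocket, mk, wild = "LYS", mut = "ARG",
                          structure_id = "bundle")),
    do.call(rbind, lapply(inward, mk, wild = "SER", mut = "ALA",
                          structure_id = "bundle")),
    if (include_gly) mk(gly_site, "GLY", "SER", "bundle"))

  expected <- data.frame(
    mutation = v$mutation, structure = v$structure,
    cluster = c(rep(2L, n_pocket), rep(2L, n_nonpocket), rep(3L, n_inward),
                if (include_gly) 3L),
    orientation = c(rep("outward", n_pocket + n_nonpocket),
                    rep("inward", n_inward),
                    if (include_gly) "inward"),
    pocket_candidate = c(rep(TRUE, n_pocket), rep(FALSE, n_nonpocket),
                         rep(FALSE, n_inward), if (include_gly) FALSE),
    status = "profiled", stringsAsFactors = FALSE)

  structures <- list(bundle = s)
  if (include_buried) {
    ball <- make_buried_site_fixture(seed = seed)
    structures$ball <- ball$structure
    v <- rbind(v, mk(ball$site$resseq, "ALA", "VAL", "ball"))
    expected <- rbind(expected, data.frame(
      mutation = v$mutation[nrow(v)], structure = "ball", cluster = 1L,
      orientation = "inward", pocket_candidate = FALSE,
      status = "profiled", stringsAsFactors = FALSE))
  }
  variants <- data.frame(
    gene = sprintf("GENE%02d", seq_len(nrow(v))),
    uniprot = sprintf("P%05d", seq_len(nrow(v))),
    mutation = v$mutation, structure = v$structure,
    chain = NA_character_, offset = 0L, stringsAsFactors = FALSE)
  list(structures = structures, variants = variants, expected = expected)
}

#' Write a structure as a PDB file
#'
#' Emits ATOM records with the stored B-factor column (pLDDT for predicted
#' models) plus a header line that lets [read_structure()] re-detect the
#' source.  Deterministic: same structure, same bytes.
#'
#' @param structure A `protein_structure`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_structure <- function(structure, file) {
  at <- structure$atoms
  name4 <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
                  sprintf(" %-3s", at$name))
  rec <- sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 at$serial, name4, at$altloc, at$resname, at$chain,
                 at$resseq, at$icode, at$x, at$y, at$z, at$occupancy,
                 at$bfactor, at$element)
  hdr <- if (structure$source == "predicted")
    sprintf("TITLE     PREDICTED MODEL %s (ALPHAFOLD-STYLE PLDDT B-FACTORS)",
            toupper(structure$id))
  else sprintf("TITLE     %s", toupper(structure$id))
  writeLines(c(hdr, rec, "TER", "END"), file)
  invisible(file)
}

#' Write a full fixture set to a directory
#'
#' Writes every structure of a [make_variant_fixture()] result as
#' `<name>.pdb`, the variant table as `variants.tsv` and the expected
#' profile as `expected.tsv`.
#'
#' @param fixture Output of [make_variant_fixture()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_files <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(fixture$structures))
    write_structure(fixture$structures[[nm]],
                    file.path(dir, paste0(nm, ".pdb")))
  utils::write.table(fixture$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$expected, file.path(dir, "expected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
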