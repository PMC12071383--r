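#' Numerical parameters for depth computation
#'
#' @param reference_radius Radius r (A) of the reference sphere centered on
#'   each atom; the depth index is twice the fraction of that sphere not
#'   occupied by the protein body.  Default 10 A puts a flat-surface atom
#'   near depth 1 and a fully exposed atom near 2.
#' @param grid_spacing Voxel edge h (A).  Must satisfy `h <= r/10`.
#' @param probe_radius Solvent probe (A) used by the cavity flood fill;
#'   channels narrower than the probe do not connect a void to bulk solvent.
#' @param fill_cavities If `TRUE` (default), solvent-inaccessible internal
#'   voids are counted as protein body.
#' @param max_voxels Memory guard: error out if the grid would exceed this
#'   many voxels (suggesting a larger `grid_spacing`).
#' @return A `depth_params` list.
#' @export
depth_params <- function(reference_radius = 10, grid_spacing = 0.5,
                         probe_radius = 1.4, fill_cavities = TRUE,
                         max_voxels = 3e8) {
  if (!is.numeric(reference_radius) || reference_radius <= 0)
    stop("reference_radius must be positive")
  if (!is.numeric(grid_spacing) || grid_spacing <= 0)
    stop("grid_spacing must be positive")
  if (grid_spacing > reference_radius / 10)
    stop("grid_spacing must be <= reference_radius/10")
  if (!is.numeric(probe_radius) || probe_radius < 0)
    stop("probe_radius must be >= 0")
  structure(list(reference_radius = reference_radius,
                 grid_spacing = grid_spacing,
                 probe_radius = probe_radius,
                 fill_cavities = isTRUE(fill_cavities),
                 max_voxels = max_voxels),
            class = "depth_params")
}

# Linear voxel-index offsets of a sphere of radius radius_h (voxel units)
# around a voxel center displaced by the fractional offset f (voxel units).
# Returns integer offsets into a (nx, ny, nz) array stored column-major.
sphere_offsets <- function(f, radius_h, nx, nxny) {
  dr <- as.integer(ceiling(radius_h + 1))
  dd <- -dr:dr
  d2 <- outer(outer((dd - f[1])^2, (dd - f[2])^2, "+"), (dd - f[3])^2, "+")
  keep <- d2 <= radius_h^2
  lin <- outer(outer(dd, dd * nx, "+"), dd * nxny, "+")
  as.integer(lin[keep])
}

# Mark voxels whose centers lie within radii[i] of atom i as TRUE.
# Atoms sharing the same sub-voxel fractional position and radius share one
# precomputed spherical stencil (exact, and fast for lattice fixtures).
mark_spheres <- function(occ, dims, origin, h, xyz, radii) {
  nx <- dims[1]; nxny <- dims[1] * dims[2]
  g <- sweep(xyz, 2, origin, "-") / h + 1
  cidx <- round(g)
  f <- g - cidx
  lc <- as.integer(cidx[, 1] + (cidx[, 2] - 1) * nx + (cidx[, 3] - 1) * nxny)
  key <- paste(round(f[, 1], 6), round(f[, 2], 6), round(f[, 3], 6),
               round(radii, 6))
  for (k in unique(key)) {
    sel <- which(key == k)
    offs <- sphere_offsets(f[sel[1], ], radii[sel[1]] / h, nx, nxny)
    tgt <- rep(lc[sel], each = length(offs)) + offs
    occ[tgt] <- TRUE
  }
  occ
}

# Linear indices of the six faces of a (nx, ny, nz) box.
boundary_indices <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nxny <- nx * ny
  jk <- as.vector(outer((0:(ny - 1)) * nx, (0:(nz - 1)) * nxny, "+"))
  ik <- as.vector(outer(1:nx, (0:(nz - 1)) * nxny, "+"))
  ij <- as.vector(outer(1:nx, (0:(ny - 1)) * nx, "+"))
  unique(as.integer(c(1 + jk, nx + jk,
                      ik, ik + (ny - 1) * nx,
                      ij, ij + (nz - 1) * nxny)))
}

# Breadth-first 6-connected flood over `open` voxels starting from seeds.
# Returns a logical vector marking reached voxels.
flood_fill6 <- function(open, dims, seeds) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nxny <- nx * ny
  visited <- logical(length(open))
  frontier <- seeds[open[seeds]]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    i0 <- frontier - 1L
    ix <- i0 %% nx
    iy <- (i0 %/% nx) %% ny
    iz <- i0 %/% nxny
    nb <- c(frontier[ix > 0L] - 1L,
            frontier[ix < nx - 1L] + 1L,
            frontier[iy > 0L] - nx,
            frontier[iy < ny - 1L] + nx,
            frontier[iz > 0L] - nxny,
            frontier[iz < nz - 1L] + nxny)
    nb <- nb[open[nb] & !visited[nb]]
    if (!length(nb)) break
    nb <- unique(nb)
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

#' Voxelize a structure into an occupancy grid
#'
#' A voxel is protein-occupied when its center lies within the van der
#' Waals radius of any atom.  With `fill_cavities`, internal voids that a
#' solvent probe cannot reach from outside are also marked occupied: the
#' probe-accessible region (voxel centers at least `probe_radius` beyond
#' every atom surface) is flood-filled from the box boundary, dilated back
#' to the protein surface by the probe radius, and every free voxel outside
#' that solvent region is counted as body.  The grid box extends
#' `reference_radius + max(vdw)` beyond every atom so that reference
#' spheres of all atoms fit inside it.
#'
#' @param structure A `protein_structure`.
#' @param params A [depth_params()] object.
#' @return An `occupancy_grid`: list with `origin` (center of voxel
#'   (1,1,1)), `spacing`, `dim` and logical 3-D `occupancy` array.
#' @export
voxelize <- function(structure, params = depth_params()) {
  at <- structure$atoms
  if (!nrow(at)) stop("empty structure")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates in structure")
  vdw <- at$vdw
  h <- params$grid_spacing
  r <- params$reference_radius
  if (r <= max(vdw))
    stop("reference_radius must exceed the largest van der Waals radius")
  pad <- r + max(vdw) + h
  origin <- apply(xyz, 2, min) - pad
  upper <- apply(xyz, 2, max) + pad
  dims <- as.integer(ceiling((upper - origin) / h)) + 1L
  nvox <- prod(as.double(dims))
  if (nvox > params$max_voxels)
    stop(sprintf(paste0("voxel grid of %.0f voxels exceeds the memory budget ",
                        "(%.0f); increase grid_spacing"),
                 nvox, params$max_voxels))

  occ <- mark_spheres(array(FALSE, dims), dims, origin, h, xyz, vdw)

  if (params$fill_cavities) {
    probe <- params$probe_radius
    acc_blocked <- mark_spheres(array(FALSE, dims), dims, origin, h, xyz,
                                vdw + probe)
    reach <- flood_fill6(!acc_blocked, dims, boundary_indices(dims))
    u <- which(!occ & !reach)
    if (length(u)) {
      # solvent = probe-dilation of the reachable accessible region
      # (half a voxel diagonal of slack absorbs grid quantization)
      offs <- sphere_offsets(c(0, 0, 0), probe / h + sqrt(3) / 2, dims[1],
                             dims[1] * dims[2])
      solvent <- logical(length(u))
      for (o in offs) solvent <- solvent | reach[u + o]
      occ[u[!solvent]] <- TRUE
    }
  }
  structure(list(origin = origin, spacing = h, dim = dims, occupancy = occ),
            class = "occupancy_grid")
}

#' Per-atom exposed-volume depth indices
#'
#' For each heavy atom the depth index is
#' `D_i = 2 * V_exposed / V_sphere`, estimated on the voxel grid as twice
#' the fraction of voxel centers within `reference_radius` of the atom
#' center that are not occupied by the (cavity-filled) protein body.  A
#' fully exposed atom scores close to 2, an atom on a flat surface close
#' to 1, and a fully buried atom 0.  Deterministic for fixed parameters.
#'
#' @param structure A `protein_structure`.
#' @param params A [depth_params()] object.
#' @param grid Optional precomputed [voxelize()] grid (must have been built
#'   from the same structure and parameters).
#' @param serials Optional subset of atom serials to compute; default all.
#' @return Named numeric vector of depth indices in `[0, 2]`, names = atom
#'   serials, in structure order.
#' @export
compute_atom_depths <- function(structure, params = depth_params(),
                                grid = NULL, serials = NULL) {
  if (is.null(grid)) grid <- voxelize(structure, params)
  occ <- grid$occupancy
  dims <- grid$dim
  h <- grid$spacing
  nx <- dims[1]; nxny <- dims[1] * dims[2]
  at <- structure$atoms
  if (!is.null(serials)) {
    at <- at[at$serial %in% serials, , drop = FALSE]
    if (!nrow(at)) stop("no atoms match the requested serials")
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  g <- sweep(xyz, 2, grid$origin, "-") / h + 1
  cidx <- round(g)
  f <- g - cidx
  lc <- as.integer(cidx[, 1] + (cidx[, 2] - 1) * nx + (cidx[, 3] - 1) * nxny)
  rh <- params$reference_radius / h
  key <- paste(round(f[, 1], 6), round(f[, 2], 6), round(f[, 3], 6))
  d <- numeric(nrow(at))
  for (k in unique(key)) {
    sel <- which(key == k)
    offs <- sphere_offsets(f[sel[1], ], rh, nx, nxny)
    n_in <- length(offs)
    for (i in sel) d[i] <- 2 * sum(!occ[lc[i] + offs]) / n_in
  }
  names(d) <- at$serial
  d
}

#' Residue-level depth summary
#'
#' Summarizes a residue by the depth of its C-alpha atom (`d_alpha`), the
#' arithmetic mean depth of its side-chain heavy atoms (`d_sc`; all heavy
#' atoms except N, CA, C, O and OXT, so CB is included), and their ratio
#' `d_sc / d_alpha` (reported when `d_alpha > 0`).  For glycine, which has
#' no side-chain heavy atom, `d_sc` is set equal to `d_alpha` by
#' convention.
#'
#' @param structure A `protein_structure`.
#' @param depths Named depth vector from [compute_atom_depths()].
#' @param chain,resseq,icode Residue selector (author numbering).
#' @return A `residue_depth` list: chain, resseq, icode, resname, d_alpha,
#'   d_sc, ratio.
#' @export
residue_depth_profile <- function(structure, depths, chain, resseq,
                                  icode = " ") {
  rows <- residue_rows(structure, chain, resseq, icode)
  if (!length(rows))
    stop(sprintf("residue %s/%s%s not found in structure '%s'",
                 chain, resseq, trimws(icode), structure$id))
  at <- structure$atoms[rows, , drop = FALSE]
  resname <- at$resname[1]
  ca <- which(at$name == "CA")
  if (!length(ca)) stop(sprintf("residue %s/%s has no CA atom", chain, resseq))
  d_alpha <- unname(depths[as.character(at$serial[ca[1]])])
  if (is.na(d_alpha))
    stop(sprintf("no depth value for CA of residue %s/%s", chain, resseq))
  if (resname == "GLY") {
    d_sc <- d_alpha
  } else {
    sc <- which(!(at$name %in% BACKBONE_ATOMS))
    if (!length(sc)) {
      warning(sprintf("residue %s/%s (%s) has no side-chain atoms; using d_alpha",
                      chain, resseq, resname))
      d_sc <- d_alpha
    } else {
      dv <- depths[as.character(at$serial[sc])]
      if (anyNA(dv)) {
        warning(sprintf("residue %s/%s: %d side-chain atom(s) without depth; mean over present atoms",
                        chain, resseq, sum(is.na(dv))))
        dv <- dv[!is.na(dv)]
        if (!length(dv)) stop(sprintf(
          "residue %s/%s: no side-chain depth values available", chain, resseq))
      }
      d_sc <- mean(unname(dv))
    }
  }
  structure(list(chain = chain, resseq = resseq, icode = icode,
                 resname = resname, d_alpha = d_alpha, d_sc = d_sc,
                 ratio = if (d_alpha > 0) d_sc / d_alpha else NA_real_),
            class = "residue_depth")
}

#' @export
print.residue_depth <- function(x, ...) {
  cat(sprintf("<residue_depth> %s %s/%s  d_alpha=%.3f  d_sc=%.3f  ratio=%s\n",
              x$resname, x$chain, x$resseq, x$d_alpha, x$d_sc,
              if (is.na(x$ratio)) "NA" else sprintf("%.2f", x$ratio)))
  invisible(x)
}

#' Tabulate per-atom depths
#'
#' @param structure A `protein_structure`.
#' @param depths Named depth vector from [compute_atom_depths()].
#' @return Data frame with serial, name, chain, resseq, resname, depth.
#' @export
depth_table <- function(structure, depths) {
  at <- structure$atoms
  data.frame(serial = at$serial, name = at$name, chain = at$chain,
             resseq = at$resseq, resname = at$resname,
             depth = unname(depths[as.character(at$serial)]),
             stringsAsFactors = FALSE)
}
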