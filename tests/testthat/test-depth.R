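test_that("depth parameters are validated", {
  expect_error(depth_params(grid_spacing = 2), "grid_spacing")
  expect_error(depth_params(reference_radius = -1), "reference_radius")
  expect_error(depth_params(probe_radius = -0.1), "probe_radius")
  expect_error(
    voxelize(make_geometric_fixture("single_atom")$structure,
             depth_params(max_voxels = 1000)),
    "grid_spacing")
})

test_that("voxelized single-atom volume matches the analytic sphere volume", {
  fx <- make_geometric_fixture("single_atom")
  g <- voxelize(fx$structure, depth_params(grid_spacing = 0.5))
  vol <- sum(g$occupancy) * g$spacing^3
  expect_equal(vol, 4 / 3 * pi * 1.7^3, tolerance = 0.1)
})

test_that("cavity filling marks enclosed voids as body, and only those", {
  sh <- make_geometric_fixture("shell_with_cavity")
  p_fill <- depth_params()
  p_open <- depth_params(fill_cavities = FALSE)
  g_fill <- voxelize(sh$structure, p_fill)
  g_open <- voxelize(sh$structure, p_open)
  # voxels well inside the cavity
  ctr <- round((sh$cavity_center - g_fill$origin) / g_fill$spacing) + 1
  lin <- function(i, j, k, d) i + (j - 1) * d[1] + (k - 1) * d[1] * d[2]
  inner <- lin(ctr[1], ctr[2], ctr[3], g_fill$dim) +
    c(0, 1, -1, g_fill$dim[1], -g_fill$dim[1])
  expect_true(all(g_fill$occupancy[inner]))
  expect_false(any(g_open$occupancy[inner]))
  # flood-fill oracle: after filling, no free voxel is enclosed
  reach <- shift_flood(!g_fill$occupancy)
  expect_true(all(reach[!g_fill$occupancy]))
  # without filling, the cavity voxels are exactly the enclosed free ones
  reach_open <- shift_flood(!g_open$occupancy)
  enclosed <- !g_open$occupancy & !reach_open
  expect_true(any(enclosed))
  expect_true(all(g_fill$occupancy[enclosed]))
})

test_that("analytic depth oracles hold on the geometric fixtures", {
  fx <- make_geometric_fixture("single_atom")
  d1 <- compute_atom_depths(fx$structure)
  expect_equal(unname(d1), fx$expected_depth, tolerance = 0.02)

  fb <- make_geometric_fixture("lattice_ball", radius = 5, spacing = 1)
  db <- compute_atom_depths(fb$structure, serials = 1L)
  expect_equal(unname(db), 1.75, tolerance = 0.05)
})

test_that("depths stay in [0, 2] and never increase when atoms are added", {
  base <- random_blob(n = 25, sd = 4, seed = 11)
  d_base <- compute_atom_depths(base)
  expect_true(all(d_base >= 0 & d_base <= 2))
  # add interior atoms without changing the bounding box, so the voxel
  # lattice is identical and monotonicity must hold exactly
  set.seed(12)
  extra <- matrix(stats::runif(3 * 10, -1.5, 1.5), ncol = 3)
  at <- base$atoms
  grown <- sitedepth:::new_structure(
    c(at$x, extra[, 1]), c(at$y, extra[, 2]), c(at$z, extra[, 3]),
    id = "blob-grown")
  stopifnot(identical(range(grown$atoms$x), range(at$x)) ||
              all(abs(range(grown$atoms$x) - range(at$x)) < 1e-9))
  d_grown <- compute_atom_depths(grown, serials = at$serial)
  expect_true(all(d_grown <= d_base + 1e-12))
})

test_that("depths are invariant under rigid motion up to grid quantization", {
  s <- random_blob(n = 30, sd = 3, seed = 42)
  probe <- c(1L, 5L, 17L, 23L, 30L)
  d0 <- compute_atom_depths(s, serials = probe)
  th <- 0.7; ph <- 0.3
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% (rz %*% rx)
  xyz <- sweep(xyz, 2, c(0.31, 7.123, -2.71), "+")
  s2 <- sitedepth:::new_structure(xyz[, 1], xyz[, 2], xyz[, 3],
                                  id = "blob-moved")
  d1 <- compute_atom_depths(s2, serials = probe)
  expect_true(all(abs(d1 - d0) <= 0.05))
})

test_that("halving the grid spacing changes the single-atom depth by <= 0.02", {
  fx <- make_geometric_fixture("single_atom")
  d5 <- compute_atom_depths(fx$structure, depth_params(grid_spacing = 0.5))
  d25 <- compute_atom_depths(fx$structure, depth_params(grid_spacing = 0.25))
  expect_lt(abs(d5 - d25), 0.02)
})

test_that("voxel depths agree with the Monte-Carlo oracle within 3 sigma", {
  s <- random_blob(n = 30, sd = 3, seed = 42)
  # identical body definition on both routes: plain union of vdW spheres
  d <- compute_atom_depths(s, depth_params(grid_spacing = 0.25,
                                           fill_cavities = FALSE),
                           serials = c(1L, 5L, 17L))
  for (sr in c(1, 5, 17)) {
    m <- mc_depth(s, sr, nsamp = 1e5)
    expect_lt(abs(d[as.character(sr)] - m$depth), 3 * m$se)
  }
})

test_that("residue depth summary applies the Gly convention and side-chain mean", {
  s <- parse_structure(synth_pdb(list(list(resseq = 1, resname = "GLY"),
                                      list(resseq = 2, resname = "VAL"))))
  at <- s$atoms
  d <- numeric(nrow(at)); names(d) <- at$serial
  d[at$resseq == 1 & at$name == "CA"] <- 0.4
  d[at$resseq == 2 & at$name == "CA"] <- 0.3
  d[at$resseq == 2 & at$name == "CB"] <- 0.8
  d[at$resseq == 2 & at$name == "CG1"] <- 1.0
  d[at$resseq == 2 & at$name == "CG2"] <- 1.2
  gly <- residue_depth_profile(s, d, "A", 1)
  expect_equal(gly$d_sc, gly$d_alpha)
  expect_equal(gly$ratio, 1)
  val <- residue_depth_profile(s, d, "A", 2)
  expect_equal(val$d_sc, 1.0)
  expect_equal(val$ratio, 1 / 0.3, tolerance = 1e-9)
  expect_error(residue_depth_profile(s, d, "A", 99), "not found")
  # missing side-chain depths: warn, average over present atoms
  d2 <- d
  d2[at$resseq == 2 & at$name == "CG2"] <- NA
  expect_warning(v2 <- residue_depth_profile(s, d2, "A", 2), "side-chain")
  expect_equal(v2$d_sc, 0.9)
  # a CA without depth value is an error
  d3 <- d
  d3[at$resseq == 2 & at$name == "CA"] <- NA
  expect_error(residue_depth_profile(s, d3, "A", 2), "CA")
})
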