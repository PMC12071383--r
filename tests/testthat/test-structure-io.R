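test_that("ATOM records parse; HETATM, hydrogens and later models are dropped", {
  ala <- synth_pdb(list(list(resseq = 1, resname = "ALA")))
  s <- parse_structure(ala)
  expect_s3_class(s, "protein_structure")
  expect_equal(nrow(s$atoms), 5)
  expect_equal(unique(s$atoms$resname), "ALA")

  withhet <- c(ala,
               pdb_atom_line(90, "O", "HOH", "A", 200, 1, 1, 1,
                             element = "O", record = "HETATM"),
               pdb_atom_line(91, "HB1", "ALA", "A", 1, 2, 2, 2,
                             element = "H"))
  s2 <- parse_structure(withhet)
  expect_equal(s2$atoms[, c("name", "x", "y", "z")],
               s$atoms[, c("name", "x", "y", "z")])

  multi <- c("MODEL     1", ala, "ENDMDL", "MODEL     2",
             synth_pdb(list(list(resseq = 2, resname = "GLY"))), "ENDMDL")
  expect_equal(nrow(parse_structure(multi)$atoms), 5)
})

test_that("parsing tolerates trailing whitespace and missing element columns", {
  lines <- synth_pdb(list(list(resseq = 3, resname = "VAL")))
  ref <- parse_structure(lines)
  stripped <- paste0(substr(lines, 1, 66), "   ")  # drop cols 67-80, add junk
  s <- parse_structure(stripped)
  expect_equal(s$atoms$element, ref$atoms$element)
  expect_equal(s$atoms$x, ref$atoms$x)
  expect_equal(s$atoms$vdw, ref$atoms$vdw)
})

test_that("alternate locations keep the highest occupancy, ties keep the first", {
  base <- synth_pdb(list(list(resseq = 1, resname = "ALA")))
  # replace CB with two conformers, A at 0.4 and B at 0.6
  cb_a <- pdb_atom_line(5, "CB", "ALA", "A", 1, 5, 5, 5, occ = 0.4,
                        element = "C", altloc = "A")
  cb_b <- pdb_atom_line(6, "CB", "ALA", "A", 1, 6, 6, 6, occ = 0.6,
                        element = "C", altloc = "B")
  s <- parse_structure(c(base[1:4], cb_a, cb_b))
  cb <- s$atoms[s$atoms$name == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$altloc, "B")
  expect_equal(cb$x, 6)
  # tie: first encountered wins
  cb_b2 <- pdb_atom_line(6, "CB", "ALA", "A", 1, 6, 6, 6, occ = 0.4,
                         element = "C", altloc = "B")
  s2 <- parse_structure(c(base[1:4], cb_a, cb_b2))
  expect_equal(s2$atoms[s2$atoms$name == "CB", "altloc"], "A")
})

test_that("parse errors carry their cause", {
  expect_error(parse_structure(c("HEADER foo", "END")), "no ATOM records")
  bad <- synth_pdb(list(list(resseq = 1, resname = "ALA")))
  substr(bad[2], 31, 38) <- "  xx.yyy"
  expect_error(parse_structure(bad), "line 2")
  # CA-less structures are rejected
  noca <- pdb_atom_line(1, "CB", "ALA", "A", 1, 0, 0, 0, element = "C")
  expect_error(parse_structure(noca), "CA")
})

test_that("heavy-atom counts match canonical residue composition", {
  s <- parse_structure(synth_pdb(list(
    list(resseq = 1, resname = "TRP"),
    list(resseq = 2, resname = "GLY"),
    list(resseq = 3, resname = "VAL"))))
  counts <- table(s$atoms$resname)
  expect_equal(unname(counts[["TRP"]]), 14)
  expect_equal(unname(counts[["GLY"]]), 4)
  expect_equal(unname(counts[["VAL"]]), 7)
})

test_that("depth-annotated output round-trips and formats the B-factor column", {
  s <- parse_structure(synth_pdb(list(list(resseq = 1, resname = "VAL"),
                                      list(resseq = 2, resname = "GLY"))))
  d <- seq(0.05, by = 0.17, length.out = nrow(s$atoms))
  names(d) <- s$atoms$serial
  out <- write_depth_annotated(s, d)
  s2 <- parse_structure(out)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(s2$atoms$y, s$atoms$y, tolerance = 1e-3)
  expect_equal(s2$atoms$z, s$atoms$z, tolerance = 1e-3)
  expect_equal(s2$atoms$bfactor, round(unname(d), 2))

  one <- parse_structure(synth_pdb(list(list(resseq = 1, resname = "GLY"))))
  rec <- write_depth_annotated(one, stats::setNames(rep(1.99, 4),
                                                    one$atoms$serial))
  expect_match(substr(rec[1], 61, 66), "1.99")

  dmiss <- d[-3]
  expect_error(write_depth_annotated(s, dmiss),
               as.character(s$atoms$serial[3]))
})

test_that("pLDDT extraction averages per residue and detects the 0-100 scale", {
  res <- list(list(resseq = 1, resname = "GLY"),
              list(resseq = 2, resname = "GLY"))
  s100 <- parse_structure(synth_pdb(res, b = c(92, 80)), source = "predicted")
  p <- extract_plddt(s100)
  expect_equal(p$plddt, c(0.92, 0.80))
  s1 <- parse_structure(synth_pdb(res, b = c(0.85, 0.70)),
                        source = "predicted")
  expect_equal(extract_plddt(s1)$plddt, c(0.85, 0.70))
  sneg <- parse_structure(synth_pdb(res, b = c(-1, 0.5)),
                          source = "predicted")
  expect_error(extract_plddt(sneg), "negative")
  sexp <- parse_structure(synth_pdb(res, b = c(92, 80)))
  expect_error(extract_plddt(sexp), "predicted")
})

test_that("parser agrees with bio3d on a written structure", {
  fix <- make_geometric_fixture("lattice_ball", radius = 4, spacing = 1.5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fix$structure, path)
  ours <- read_structure(path)
  theirs <- bio3d::read.pdb(path)
  expect_equal(nrow(ours$atoms), nrow(theirs$atom))
  expect_equal(ours$atoms$x, theirs$atom$x, tolerance = 1e-6)
  expect_equal(ours$atoms$y, theirs$atom$y, tolerance = 1e-6)
  expect_equal(ours$atoms$z, theirs$atom$z, tolerance = 1e-6)
})
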