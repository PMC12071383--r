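test_that("mutation notation parses and validates", {
  p <- parse_mutation_notation(c("Val149Gly", "Trp262Gly", "ALA10ser"))
  expect_equal(p$wild_aa, c("VAL", "TRP", "ALA"))
  expect_equal(p$position, c(149L, 262L, 10L))
  expect_equal(p$mutant_aa, c("GLY", "GLY", "SER"))
  expect_error(parse_mutation_notation("Xyz10Ala"), "XYZ")
  expect_error(parse_mutation_notation("Ala0Gly"), "positive")
  expect_error(parse_mutation_notation("A149G"), "malformed")
  expect_error(parse_mutation_notation("Val149"), "malformed")
})

test_that("sites map onto structures with identity check and offset", {
  s <- parse_structure(synth_pdb(list(list(resseq = 107, resname = "TRP"),
                                      list(resseq = 108, resname = "ARG"),
                                      list(resseq = 149, resname = "VAL"))))
  ok <- map_site_to_structure(s, "VAL", 149)
  expect_equal(ok$status, "ok")
  mism <- map_site_to_structure(s, "TRP", 108)
  expect_equal(mism$status, "residue_mismatch")
  expect_equal(mism$found, "ARG")
  # the numbering offset resolves author-vs-sequence discrepancies
  off <- map_site_to_structure(s, "TRP", 108, offset = -1)
  expect_equal(off$status, "ok")
  expect_equal(off$resseq, 107)
  expect_equal(map_site_to_structure(s, "ALA", 500)$status, "missing_residue")
})

test_that("pLDDT filter requires both chain mean and site above threshold", {
  res <- lapply(1:4, function(i) list(resseq = i, resname = "GLY"))
  # mean 0.85, site 1 at 0.90 -> pass
  s <- parse_structure(synth_pdb(res, b = c(0.90, 0.85, 0.85, 0.80)),
                       source = "predicted")
  expect_true(apply_plddt_filter(s, 1))
  # site below threshold -> fail despite good mean
  s2 <- parse_structure(synth_pdb(res, b = c(0.79, 0.95, 0.95, 0.95)),
                        source = "predicted")
  expect_false(apply_plddt_filter(s2, 1))
  # mean exactly at threshold fails the strict comparison
  s3 <- parse_structure(synth_pdb(res, b = c(0.95, 0.75, 0.75, 0.75)),
                        source = "predicted")
  expect_equal(mean(extract_plddt(s3)$plddt), 0.8)
  expect_false(apply_plddt_filter(s3, 1))
  # experimental structures pass automatically
  s4 <- parse_structure(synth_pdb(res, b = 0))
  expect_true(apply_plddt_filter(s4, 1))
})

test_that("profiling conserves records, caches deterministically, and keeps reasons", {
  fix <- make_variant_fixture(seed = 3, n_pocket = 2, n_nonpocket = 1,
                              n_inward = 1, include_buried = FALSE)
  v <- fix$variants
  # duplicate a record and add a mismatching and a structureless one
  v2 <- rbind(v, v[1, ], v[1, ], v[1, ])
  v2$mutation[nrow(v) + 2] <- sub("^Trp", "Tyr", v2$mutation[nrow(v) + 2])
  v2$structure[nrow(v) + 3] <- "no_such_structure"
  prof <- profile_variants(v2, fix$structures)
  expect_equal(nrow(prof), nrow(v2))
  expect_equal(prof$mutation, v2$mutation)
  # identical record profiled twice yields identical rows
  expect_equal(prof[1, ], prof[nrow(v) + 1, ], ignore_attr = TRUE)
  expect_equal(prof$status[nrow(v) + 2], "residue_mismatch")
  expect_equal(prof$status[nrow(v) + 3], "missing_structure")
  # profiled rows are fully populated; failed rows carry no cluster
  expect_true(all(!is.na(prof$cluster[prof$status == "profiled"])))
  expect_true(all(is.na(prof$cluster[prof$status != "profiled"])))
  # the mismatching record was never silently profiled with the wrong residue
  expect_false(prof$status[nrow(v) + 2] == "profiled")
  # whole-table determinism
  prof2 <- profile_variants(v2, fix$structures)
  expect_identical(prof, prof2)
})

test_that("pLDDT-filtered sites carry the reason and no cluster", {
  res <- lapply(1:4, function(i) list(resseq = i, resname = "ALA"))
  s <- parse_structure(synth_pdb(res, b = c(0.5, 0.95, 0.95, 0.95)),
                       source = "predicted")
  v <- data.frame(gene = "G1", uniprot = "P1", mutation = "Ala1Val",
                  structure = "m", chain = NA, offset = 0L,
                  stringsAsFactors = FALSE)
  prof <- profile_variants(v, list(m = s))
  expect_equal(prof$status, "plddt_filtered")
  expect_true(is.na(prof$cluster))
})

test_that("an empty record list gives an empty table, not an error", {
  v <- data.frame(gene = character(0), uniprot = character(0),
                  mutation = character(0), structure = character(0),
                  stringsAsFactors = FALSE)
  prof <- profile_variants(v, list())
  expect_s3_class(prof, "profile_table")
  expect_equal(nrow(prof), 0)
})

test_that("variant tables and profile TSVs round-trip through disk", {
  dir <- withr::local_tempdir()
  fix <- make_variant_fixture(seed = 5, n_pocket = 1, n_nonpocket = 1,
                              n_inward = 1, include_gly = FALSE,
                              include_buried = FALSE)
  write_fixture_files(fix, dir)
  v <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_equal(v$mutation, fix$variants$mutation)
  # profiling from the written directory equals profiling from memory
  prof_mem <- profile_variants(fix$variants, fix$structures)
  prof_dir <- profile_variants(v, dir)
  expect_equal(prof_dir$cluster, prof_mem$cluster)
  # PDB coordinates are written to 3 decimals, which can shift individual
  # voxel memberships; depths agree to grid tolerance
  expect_equal(prof_dir$d_alpha, prof_mem$d_alpha, tolerance = 0.02)
  path <- file.path(dir, "profile.tsv")
  write_profile_tsv(prof_mem, path)
  back <- read_profile_tsv(path)
  expect_equal(back$cluster, prof_mem$cluster)
  expect_equal(back$pocket_candidate, prof_mem$pocket_candidate)
  expect_equal(back$d_alpha, round(prof_mem$d_alpha, 3))
})
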