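test_that("crystal unit and bundle counts follow the builder products", {
  u <- build_crystal_unit(builder_spec())
  expect_equal(n_chains(u), 25)
  expect_equal(n_residues(u), 200)

  u1 <- build_crystal_unit(builder_spec(strands_per_sheet = 1,
                                        sheets_per_unit = 1,
                                        polyala_length = 1))
  expect_equal(n_chains(u1), 1)
  expect_equal(n_residues(u1), 1)

  u2 <- build_crystal_unit(builder_spec(strands_per_sheet = 2,
                                        sheets_per_unit = 3,
                                        polyala_length = 4))
  expect_equal(n_chains(u2), 6)
  expect_equal(n_residues(u2), 24)

  b <- build_amorphous_bundle(builder_spec())
  expect_equal(n_chains(b), 8)
  expect_equal(n_residues(b), 192)
  expect_equal(n_chains(build_amorphous_bundle(builder_spec(chains_per_bundle = 1))), 1)

  # fully extended chain: end-to-end CA span = (n_res - 1) * rise
  ca <- dplyr::filter(b, atom == "CA", chain_id == b$chain_id[1])
  expect_equal(diff(range(ca$y)), 23 * 0.35, tolerance = 1e-10)
})

test_that("the full composite has 50 crystalline and 56 amorphous chains", {
  comp <- full_composite()
  ph <- dplyr::distinct(comp[, c("chain_id", "phase")])
  expect_equal(sum(ph$phase == "crystalline"), 50)
  expect_equal(sum(ph$phase == "amorphous"), 56)
  # phase partition: every atom tagged, tags consistent per chain
  expect_true(all(comp$phase %in% c("crystalline", "amorphous")))
  expect_equal(nrow(ph), 106)
})

test_that("crystal units sit at the prescribed surface separation", {
  comp <- full_composite()
  cr <- structure_phase(comp, "crystalline")
  ids <- sort(unique(cr$chain_id))
  u1 <- dplyr::filter(cr, chain_id %in% ids[1:25])
  u2 <- dplyr::filter(cr, chain_id %in% ids[26:50])
  gap <- silkfric:::.min_cross_dist(u1, u2, cutoff = 4)
  expect_gte(gap, 2.9)
  expect_lte(gap, 3.1)
})

test_that("crystalline-only assemblies and clash guards work", {
  solo <- assemble_composite(builder_spec(n_units = 1, n_bundles = 0))
  expect_true(all(solo$phase == "crystalline"))
  expect_equal(n_chains(solo), 25)
  # forcing bundles into the crystal volume must raise a placement clash
  expect_error(assemble_composite(small_spec(), clearance = -2),
               "clash")
})

test_that("the builder is deterministic and validates its inputs", {
  a <- assemble_composite(small_spec())
  b <- assemble_composite(small_spec())
  expect_identical(as.data.frame(a), as.data.frame(b))

  expect_error(builder_spec(strands_per_sheet = 0), "positive integers")
  expect_error(builder_spec(polyala_length = 2.5), "positive integers")
  expect_error(builder_spec(unit_gap = -1), "unit_gap")
  expect_error(builder_spec(amorphous_sequence = "GXZ!"), "amino-acid")
})

test_that("PDB round trip preserves coordinates, chains and phase tags", {
  comp <- small_composite()
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  write_pdb(comp, tmp)
  back <- read_pdb(tmp)
  expect_equal(nrow(back), nrow(comp))
  expect_equal(back$chain_id, comp$chain_id)
  expect_equal(back$phase, comp$phase)
  expect_lt(max(abs(back$x - comp$x), abs(back$y - comp$y),
                abs(back$z - comp$z)), 1e-3)
  expect_error(write_pdb(comp[0, ], tempfile()), "empty")
})

test_that("malformed PDB input reports the offending line", {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(c("ATOM      1  CA  ALA A   1      xx.yyy   0.000   0.000",
               "END"), tmp)
  expect_error(read_pdb(tmp), "line 1")
  expect_error(read_pdb("no/such/file.pdb"), "no such file")
})
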