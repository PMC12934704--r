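test_that("PDB round-trip preserves coordinates, altlocs and split groups", {
  fx <- beadFixture("none", seed = 1)
  p <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(fx$truth, p)
  back <- readEnsemblePDB(p, library = beadLibrary())
  expect_equal(nAtoms(back), nAtoms(fx$truth))
  expect_lt(max(abs(coords(back) - coords(fx$truth))), 1e-3)
  expect_identical(atoms(back)$alt, atoms(fx$truth)$alt)
  expect_identical(splitGroups(back)$key, splitGroups(fx$truth)$key)
})

test_that("reader builds split groups, templates and links correctly", {
  m <- aaToyModel()
  p <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemblePDB(m, p)
  back <- readEnsemblePDB(p, library = aminoLibrary())
  sg <- splitGroups(back)
  expect_equal(nrow(sg), 1)            # only ALA1 CB is split
  expect_match(sg$key, "ALA\\|CB")
  b <- bonds(back)
  expect_equal(sum(b$kind == "link"), 1)  # one peptide bond A1-A2
  expect_equal(sum(b$kind == "ss"), 1)    # one disulfide across chains
  # a model with no altlocs has no split groups and only cognate bonds
  single <- ensembleModel(atoms(m)[atoms(m)$alt %in% c("", "A"), ],
                          library = aminoLibrary())
  expect_equal(nrow(splitGroups(single)), 0)
})

test_that("reader rejects malformed records and warns on bad occupancy", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1      bad_coordinates_here",
               "END"), p)
  expect_error(readEnsemblePDB(p), "line 1")
  a <- atoms(aaToyModel())
  a$occ[a$alt != ""] <- 0.9            # 0.9 + 0.9 > 1
  expect_warning(ensembleModel(a, library = aminoLibrary()),
                 "occupancies sum")
})

test_that("applySwaps permutes letters only and is an involution", {
  fx <- beadFixture("none", seed = 1)
  sg <- splitGroups(fx$truth)
  key <- sg$key[3]
  sw <- swapSet(key)
  once <- applySwaps(fx$truth, sw)
  expect_identical(coords(once), coords(fx$truth))
  expect_identical(atoms(once)$occ, atoms(fx$truth)$occ)
  expect_false(identical(atoms(once)$alt, atoms(fx$truth)$alt))
  twice <- applySwaps(once, sw)
  expect_identical(atoms(twice)$alt, atoms(fx$truth)$alt)
  # empty swap set leaves the model unchanged
  expect_identical(atoms(applySwaps(fx$truth, swapSet(list())))$alt,
                   atoms(fx$truth)$alt)
  # swapping an unsplit atom is an error
  expect_error(applySwaps(aaToyModel(), swapSet("A|2||CYS|SG")),
               "not a split group")
  expect_error(swapSet(key, perm = c(A = "A", B = "A")), "bijection")
})

test_that("downstream traversal follows the chain and stops at disulfides", {
  m <- aaToyModel()
  # CA of the chain-A C-terminal residue: main chain tail plus side chain
  ds <- downstreamAtoms(m, "A|2||CYS|CA")
  expect_setequal(sub("^A\\|2\\|\\|CYS\\|", "", ds),
                  c("CA", "C", "O", "OXT", "CB", "SG"))
  # terminal atom is a singleton
  expect_identical(downstreamAtoms(m, "A|2||CYS|O"), "A|2||CYS|O")
  # CB of the chain-B cystine: down to SG but never across the S-S bond
  ds2 <- downstreamAtoms(m, "B|1||CYS|CB")
  expect_setequal(ds2, c("B|1||CYS|CB", "B|1||CYS|SG"))
  # seed is always included; unknown atoms are rejected
  expect_true("A|1||ALA|CB" %in% downstreamAtoms(m, "A|1||ALA|CB"))
  expect_error(downstreamAtoms(m, "A|9||ALA|CA"), "unknown atom")
})

test_that("assignment match is gauge-invariant and counts swapped groups", {
  fx <- beadFixture("none", seed = 1)
  tr <- fx$truth
  expect_equal(assignmentMatch(tr, tr)$percentMatch, 100)
  expect_equal(assignmentMatch(flipAllLetters(tr), tr)$percentMatch, 100)
  # flipping 10% of the groups leaves a 90% match
  sg <- splitGroups(tr)
  k <- max(1, round(0.1 * nrow(sg)))
  part <- applySwaps(tr, swapSet(list(sg$key[seq_len(k)])))
  expect_equal(assignmentMatch(part, tr)$percentMatch,
               100 * (nrow(sg) - k) / nrow(sg))
  # invariant under global flip of either argument
  expect_equal(assignmentMatch(flipAllLetters(part), tr)$percentMatch,
               assignmentMatch(part, flipAllLetters(tr))$percentMatch)
  # mismatched group sets are an error
  expect_error(assignmentMatch(tr, aaToyModel()), "differ")
})
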