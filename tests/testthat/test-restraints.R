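test_that("restraint instantiation matches hand-counted template sums", {
  fx <- beadFixture("none", seed = 1)       # 6 bead residues, 2 conformers
  r <- buildRestraints(fx$truth, beadLibrary())
  n <- 6
  # per conformer: 3 intra bonds per residue + 5 peptide links
  expect_equal(nrow(r@bonds), 2 * (3 * n + (n - 1)))
  # per conformer: 3 intra angles per residue + 2 link angles per junction
  expect_equal(nrow(r@angles), 2 * (3 * n + 2 * (n - 1)))
  expect_equal(nrow(r@torsions), 0)
  # every nonbond pair is conformer-compatible and beyond 1-4
  a <- atoms(fx$truth)
  expect_true(all(a$alt[r@nonbond$i] == a$alt[r@nonbond$j] |
                  a$alt[r@nonbond$i] == "" | a$alt[r@nonbond$j] == ""))
  # unknown residues are rejected with their name
  bad <- atoms(fx$truth); bad$resname <- "XXX"
  expect_error(ensembleModel(bad, library = beadLibrary()), "XXX")
})

test_that("water has no bonded terms beyond O-H", {
  w <- ensembleModel(
    data.frame(name = "O", resname = "HOH", chain = "W", resno = 1,
               ins = "", alt = "", occ = 1, b = 20, x = 0, y = 0, z = 0,
               element = "O"),
    library = aminoLibrary())
  r <- buildRestraints(w, aminoLibrary())
  expect_equal(nrow(r@bonds) + nrow(r@angles) + nrow(r@torsions), 0)
})

test_that("term deviates follow d = (v - v0)/sigma with E = d^2", {
  lib <- chainLibrary()
  m0 <- chainModel(d12 = 1.5)
  r0 <- buildRestraints(m0, lib)
  dv0 <- termDeviates(m0, r0)
  expect_equal(dv0$bond[1], 0, tolerance = 1e-10)
  # 2 sigma stretch: E = 4
  m2 <- chainModel(d12 = 1.5 + 2 * 0.02)
  expect_equal(termDeviates(m2, buildRestraints(m2, lib))$bond[1], 2,
               tolerance = 1e-9)
  # an 11 sigma outlier carries statistical energy 121 before clipping
  m11 <- chainModel(d12 = 1.5 + 11 * 0.02)
  d11 <- termDeviates(m11, buildRestraints(m11, lib))$bond[1]
  expect_equal(d11^2, 121, tolerance = 1e-9)
})

test_that("torsion deviates wrap to (-180, 180] and match bio3d", {
  lib <- chainLibrary()
  for (tor in c(-170, -60, 100, 179)) {
    m <- chainModel(torsion = tor)
    r <- buildRestraints(m, lib)
    dv <- termDeviates(m, r)$torsion
    expect_length(dv, 1)
    # independent oracle for the measured dihedral
    meas <- bio3d::torsion.xyz(as.numeric(t(coords(m))), atm.inc = 4)[1]
    delta <- (meas - 60) %% 360
    if (delta > 180) delta <- delta - 360
    expect_equal(abs(dv), abs(delta) / 10, tolerance = 1e-6)
    # wrapping makes the deviate invariant under full turns
    delta2 <- ((meas + 360) - 60) %% 360
    if (delta2 > 180) delta2 <- delta2 - 360
    expect_equal(abs(delta2), abs(delta), tolerance = 1e-9)
  }
})

test_that("normalized LJ energy has its -1 minimum at r0 and decays to 0", {
  expect_equal(ljEnergy(3.4, 3.4), -1, tolerance = 1e-12)
  expect_equal(ljEnergy(3.4 / 2^(1 / 6), 3.4), 2^2 - 2 * 2,
               tolerance = 1e-12)   # (r0/r)^6 = 2 -> E = 0
  expect_equal(ljEnergy(100, 3.4), 0, tolerance = 1e-6)
  expect_error(ljEnergy(0, 3.4), "coincident")
  # strictly decreasing below r0, increasing toward 0 above it
  rs <- seq(2.0, 3.4, length.out = 20)
  expect_true(all(diff(ljEnergy(rs, 3.4)) < 0))
  rs <- seq(3.4, 8, length.out = 20)
  expect_true(all(diff(ljEnergy(rs, 3.4)) > 0))
  expect_true(all(ljEnergy(seq(0.5, 10, by = 0.1), 3.4) >= -1))
})

test_that("per-atom energies double-count each term once per member atom", {
  fx <- beadFixture("single_swap", seed = 1)
  r <- buildRestraints(fx$tangled, beadLibrary())
  pae <- perAtomEnergy(fx$tangled, r)
  dv <- termDeviates(fx$tangled, r)
  lj <- as.numeric(ljEnergies(fx$tangled, r))
  expect_equal(sum(pae),
               2 * sum(dv$bond^2) + 3 * sum(dv$angle^2) + 2 * sum(lj),
               tolerance = 1e-8)
  # an isolated atom has zero energy
  iso <- ensembleModel(
    data.frame(name = "O", resname = "HOH", chain = "W", resno = 1,
               ins = "", alt = "", occ = 1, b = 20, x = 0, y = 0, z = 0,
               element = "O"),
    library = aminoLibrary())
  expect_equal(perAtomEnergy(iso, buildRestraints(iso, aminoLibrary())), 0)
})

test_that("category deviates are complete and swap-invariant", {
  fx <- beadFixture("none", seed = 1)
  devs <- categoryDeviates(fx$truth, library = beadLibrary())
  expect_setequal(names(devs),
                  c("bond", "angle", "torsion", "planarity", "chirality",
                    "omega", "cbeta", "rotamer", "ramachandran", "clash"))
  expect_gt(length(devs$bond), 0)
  expect_equal(length(devs$clash), 0)       # ground truth has no clashes
  # global letter exchange is a pure relabeling of every category
  flip <- categoryDeviates(flipAllLetters(fx$truth),
                           library = beadLibrary())
  for (cat in names(devs))
    expect_equal(sort(devs[[cat]]), sort(flip[[cat]]), tolerance = 1e-12)
})
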