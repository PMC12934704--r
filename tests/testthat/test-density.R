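oneAtomModel <- function(occ = 1, split = FALSE) {
  if (split) {
    df <- data.frame(name = "O", resname = "HOH", chain = "W", resno = 1,
                     ins = "", alt = c("A", "B"), occ = 0.5, b = 20,
                     x = 0, y = 0, z = 0, element = "O")
  } else {
    df <- data.frame(name = "O", resname = "HOH", chain = "W", resno = 1,
                     ins = "", alt = "", occ = occ, b = 20,
                     x = 0, y = 0, z = 0, element = "O")
  }
  ensembleModel(df, library = aminoLibrary())
}

test_that("a single atom synthesizes a symmetric peak of conserved mass", {
  m <- oneAtomModel()
  # grid voxels placed symmetrically about the atom at the origin
  g0 <- densityGrid(array(0, c(27, 27, 27)), origin = rep(-3.9, 3),
                    spacing = 0.3)
  g <- synthesizeDensity(m, grid = g0)
  v <- gridValues(g)
  peak <- which(v == max(v), arr.ind = TRUE)[1, ]
  pos <- gridOrigin(g) + (peak - 1) * gridSpacing(g)
  expect_lt(max(abs(pos)), 1e-9)                   # peak at the atom
  # spherical symmetry: mirror along each axis
  expect_equal(v, v[rev(seq_len(27)), , ], tolerance = 1e-9)
  expect_equal(v, v[, rev(seq_len(27)), ], tolerance = 1e-9)
  expect_equal(v, aperm(v, c(2, 1, 3)), tolerance = 1e-9)
  # total density equals occupancy * electron count (8 for oxygen)
  expect_equal(sum(v) * gridSpacing(g)^3, 8, tolerance = 1e-3)
})

test_that("density is linear: two half-atoms equal one full atom", {
  g1 <- synthesizeDensity(oneAtomModel(occ = 1), spacing = 0.3, margin = 4)
  g2 <- synthesizeDensity(oneAtomModel(split = TRUE),
                          grid = g1)
  expect_equal(gridValues(g1), gridValues(g2), tolerance = 1e-12)
})

test_that("windshield-wiper and jumping-jacks ensembles share one density", {
  spec <- fixtureSpec(nResidues = 10, seed = 3)
  wiper <- untangler:::buildTruth(spec)
  spec$mode <- "anti"
  jacks <- untangler:::buildTruth(spec)
  g1 <- synthesizeDensity(wiper)
  g2 <- synthesizeDensity(jacks, grid = g1)
  expect_lt(max(abs(gridValues(g1) - gridValues(g2))), 1e-10)
  # but their ground-truth assignments differ
  expect_lt(assignmentMatch(jacks, wiper)$percentMatch, 100)
})

test_that("density misfit is zero at the generator and grows with error", {
  fx <- beadFixture("none", seed = 2)
  tr <- fx$truth
  clean <- synthesizeDensity(tr, spacing = 0.4)
  expect_equal(as.numeric(densityMisfit(tr, clean, wantGrad = FALSE)), 0,
               tolerance = 1e-9)
  moved <- tr
  X <- coords(tr); X[5, 1] <- X[5, 1] + 3
  coords(moved) <- X
  expect_gt(as.numeric(densityMisfit(moved, clean, wantGrad = FALSE)), 1)
  # invariant under global conformer-letter exchange: why traps exist
  expect_equal(as.numeric(densityMisfit(flipAllLetters(tr), clean,
                                        wantGrad = FALSE)),
               as.numeric(densityMisfit(tr, clean, wantGrad = FALSE)),
               tolerance = 1e-12)
  expect_error(densityMisfit(tr, densityGrid(array(0, c(8, 8, 8)))),
               "empty")
})

test_that("analytic misfit gradients match finite differences to 1e-4", {
  fx <- beadFixture("none", seed = 2)
  target <- synthesizeDensity(fx$truth, spacing = 0.4)
  pert <- fx$truth
  set.seed(7)
  coords(pert) <- coords(pert) +
    matrix(rnorm(3 * nAtoms(pert), sd = 0.15), ncol = 3)
  G <- attr(densityMisfit(pert, target), "gradient")
  X <- coords(pert)
  for (k in 1:20) {
    i <- sample(nrow(X), 1); d <- sample(3, 1); h <- 1e-4
    f <- function(v) {
      Xp <- X; Xp[i, d] <- v
      p <- pert; coords(p) <- Xp
      as.numeric(densityMisfit(p, target, wantGrad = FALSE))
    }
    fd <- (f(X[i, d] + h) - f(X[i, d] - h)) / (2 * h)
    expect_lt(abs(G[i, d] - fd) / max(1e-6, abs(fd)), 1e-4)
  }
})

test_that("difference maps expose missing atoms above the noise ceiling", {
  fx <- beadFixture("none", seed = 1)
  tr <- fx$truth
  target <- fx$target                       # includes 0.2% seeded noise
  # perfect model: noise peaks stay below the max-order-statistic ceiling
  dm <- differenceMap(tr, target, threshold = 3)
  noiseCeiling <- if (nrow(dm$peaks)) max(abs(dm$peaks$height)) else 0
  expect_lt(noiseCeiling, 5)
  # deleting an atom leaves a positive peak at its position, far above it
  a <- atoms(tr)
  drop <- which(a$name == "CB" & a$resno == 3 & a$alt == "A")
  m2 <- ensembleModel(a[-drop, ], library = beadLibrary())
  dm2 <- differenceMap(m2, target, threshold = 3)
  top <- dm2$peaks[1, ]
  expect_gt(top$height, 10 * noiseCeiling)
  expect_lt(sqrt(sum((c(top$x, top$y, top$z) -
                      c(a$x[drop], a$y[drop], a$z[drop]))^2)), 0.5)
  # peak list is sorted by |height|
  expect_true(!is.unsorted(rev(abs(dm2$peaks$height))))
})

test_that("mid-swap barrier states show paired difference features", {
  fx <- beadFixture("single_swap", seed = 1)
  sites <- groupSites(fx$truth, fx$planted)
  mid <- fx$truth
  X <- coords(mid)
  pA <- X[sites[1], ]; pB <- X[sites[2], ]
  X[sites[1], ] <- 0.5 * (pA + pB) + c(0.2, 0, 0)
  X[sites[2], ] <- 0.5 * (pA + pB) - c(0.2, 0, 0)
  coords(mid) <- X
  dm <- differenceMap(mid, fx$target, threshold = 3)
  near <- sqrt((dm$peaks$x - mean(c(pA[1], pB[1])))^2 +
               (dm$peaks$y - mean(c(pA[2], pB[2])))^2 +
               (dm$peaks$z - mean(c(pA[3], pB[3])))^2) < 2.5
  expect_true(any(dm$peaks$height[near] > 3))   # green: missing density
  expect_true(any(dm$peaks$height[near] < -3))  # red: misplaced density
})

test_that("MRC maps round-trip through the mode-2 reader/writer", {
  fx <- beadFixture("none", seed = 1)
  p <- withr::local_tempfile(fileext = ".mrc")
  writeMRC(fx$target, p)
  back <- readMRC(p)
  expect_equal(dim(gridValues(back)), dim(gridValues(fx$target)))
  expect_equal(gridSpacing(back), gridSpacing(fx$target), tolerance = 1e-6)
  expect_equal(gridOrigin(back), gridOrigin(fx$target), tolerance = 1e-5)
  expect_lt(max(abs(gridValues(back) - gridValues(fx$target))) /
              max(abs(gridValues(fx$target))), 1e-6)
})
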