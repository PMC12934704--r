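# Shared fixtures, built in code and cached across test files.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(id, expr) {
  if (is.null(.fixtureCache[[id]]))
    .fixtureCache[[id]] <- force(expr)
  .fixtureCache[[id]]
}

# Standard desk-scale bead fixtures (6 residues, amplitude 0.6, 0.4 A grid).
beadFixture <- function(tangleMode = "none", seed = 1, n = 6, amp = 0.6,
                        spacing = 0.4, window = 3) {
  id <- paste("bead", tangleMode, seed, n, amp, spacing,
              paste(window, collapse = "_"), sep = "-")
  cachedFixture(id, makeToyEnsemble(
    fixtureSpec(nResidues = n, splitAmplitude = amp,
                tangleMode = tangleMode, seed = seed, spacing = spacing,
                window = window)))
}

# Hand-built two-chain amino-acid toy: chain A = ALA1 (CB split A/B) +
# CYS2 (with OXT); chain B = one CYS whose SG forms a disulfide to CYS2.
aaToyModel <- function() {
  cachedFixture("aa-toy", {
    atoms <- rbind(
      data.frame(name = c("N", "CA", "C", "O", "CB", "CB"),
                 resname = "ALA", chain = "A", resno = 1, ins = "",
                 alt = c("", "", "", "", "A", "B"),
                 occ = c(1, 1, 1, 1, 0.5, 0.5), b = 10,
                 x = c(0.0, 1.46, 2.00, 1.40, 1.90, 1.90),
                 y = c(0.0, 0.00, 1.40, 2.40, -0.80, -0.80),
                 z = c(0.0, 0.00, 0.00, 0.00, 1.20, -1.20),
                 element = c("N", "C", "C", "O", "C", "C")),
      data.frame(name = c("N", "CA", "C", "O", "OXT", "CB", "SG"),
                 resname = "CYS", chain = "A", resno = 2, ins = "",
                 alt = "", occ = 1, b = 12,
                 x = c(3.30, 4.20, 5.60, 6.50, 5.90, 4.10, 4.50),
                 y = c(1.50, 2.60, 2.20, 3.00, 1.00, 3.50, 5.20),
                 z = c(0.00, 0.00, 0.00, 0.30, -0.60, 1.20, 1.00),
                 element = c("N", "C", "C", "O", "O", "C", "S")),
      data.frame(name = c("N", "CA", "C", "O", "CB", "SG"),
                 resname = "CYS", chain = "B", resno = 1, ins = "",
                 alt = "", occ = 1, b = 12,
                 x = c(4.00, 4.50, 6.00, 6.80, 4.00, 4.60),
                 y = c(9.60, 8.90, 9.10, 9.90, 7.50, 6.50),
                 z = c(1.80, 3.00, 3.20, 3.60, 3.30, 2.50),
                 element = c("N", "C", "C", "O", "C", "S")))
    ensembleModel(atoms, library = aminoLibrary())
  })
}

# A tiny custom library + 4-atom single-conformer chain for exact
# term-deviate arithmetic (bond at v0, at 2 sigma, at 11 sigma; one
# torsion record for wrap tests).
chainLibPath <- function() {
  cachedFixture("chain-lib", {
    p <- tempfile(fileext = ".lib")
    writeLines(c(
      "residue CHN",
      "bond CHN X1 X2 1.500 0.020",
      "bond CHN X2 X3 1.500 0.020",
      "bond CHN X3 X4 1.500 0.020",
      "torsion CHN X1 X2 X3 X4 60.0 10.0 1",
      "default angle 109.5 3.0",
      "vdw C 1.70",
      "nonbond cutoff 5.0",
      "clash margin 0.4"), p)
    p
  })
}

chainModel <- function(d12 = 1.5, torsion = 60) {
  # X1-X2 along x with length d12; X3, X4 placed to give the requested
  # X1-X2-X3-X4 torsion with ideal 1.5 A bonds and 109.5 deg angles.
  p1 <- c(0, 0, 0)
  p2 <- c(d12, 0, 0)
  ang <- 109.5 * pi / 180
  p3 <- p2 + 1.5 * c(-cos(ang), sin(ang), 0)
  # torsion about the p2->p3 axis
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  u0 <- (p2 - p3) / sqrt(sum((p2 - p3)^2))
  # component of p1 direction perpendicular to the axis sets phi = 0
  ref <- (p1 - p2) - sum((p1 - p2) * axis) * axis
  ref <- ref / sqrt(sum(ref^2))
  perp <- c(axis[2] * ref[3] - axis[3] * ref[2],
            axis[3] * ref[1] - axis[1] * ref[3],
            axis[1] * ref[2] - axis[2] * ref[1])
  phi <- torsion * pi / 180
  dirn <- -cos(ang) * axis +
    sin(ang) * (cos(phi) * ref + sin(phi) * perp)
  p4 <- p3 + 1.5 * dirn
  pos <- rbind(p1, p2, p3, p4)
  ensembleModel(
    data.frame(name = c("X1", "X2", "X3", "X4"), resname = "CHN",
               chain = "A", resno = 1, ins = "", alt = "", occ = 1,
               b = 10, x = pos[, 1], y = pos[, 2], z = pos[, 3],
               element = "C"),
    library = readRestraintLibrary(chainLibPath()))
}

chainLibrary <- function() readRestraintLibrary(chainLibPath())

# Global conformer-letter flip of every split group.
flipAllLetters <- function(model) {
  sg <- splitGroups(model)
  applySwaps(model, swapSet(list(sg$key)))
}
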