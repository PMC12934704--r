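test_that("clip plateau is identity below 10 and logarithmic above", {
  expect_identical(clipEnergy(4), 4)
  expect_identical(clipEnergy(10), 10)
  expect_equal(clipEnergy(10 + 1e-9), 10, tolerance = 1e-8)  # continuity
  E <- seq(0, 500, by = 0.5)
  expect_true(all(diff(clipEnergy(E)) > 0))                  # monotone
  expect_true(all(clipEnergy(E) <= E + 1e-12))
  # derivative <= 1 beyond the knee
  expect_true(all(diff(clipEnergy(seq(10, 500, by = 0.1))) <= 0.1 + 1e-9))
  # the printed trade-off: fixing a 6-sigma outlier to 3 sigma outweighs
  # nudging a 20-sigma outlier to 20.4
  expect_gt(clipEnergy(36) - clipEnergy(9),
            clipEnergy(20.4^2) - clipEnergy(20^2))
  expect_error(clipEnergy(-1), "non-negative")
})

test_that("softPnn is the max-order-statistic probability", {
  expect_equal(softPnn(6, 100), 1, tolerance = 1e-3)
  expect_equal(softPnn(1, 100), 0, tolerance = 1e-3)
  # at the median of the max-of-n null distribution the weight is 1/2
  n <- 25
  dMedian <- qnorm((1 + 0.5^(1 / n)) / 2)
  expect_equal(softPnn(dMedian, n), 0.5, tolerance = 1e-12)
  # monotone increasing in d, decreasing in n
  expect_true(all(diff(softPnn(seq(0, 6, by = 0.1), 30)) >= 0))
  expect_gt(softPnn(2.5, 10), softPnn(2.5, 1000))
})

test_that("chi-square weight is calibrated at the null median", {
  expect_equal(chi2Weight(rep(0, 30)), 0, tolerance = 1e-12)
  devs <- rep(sqrt(qchisq(0.5, 100) / 100), 100)
  expect_equal(chi2Weight(devs), 0.5, tolerance = 1e-9)
  expect_gt(chi2Weight(rep(5, 50)), 0.999)
  # two-sided tail probability conversion for probability categories
  expect_equal(probToDeviate(2 * (1 - pnorm(1))), 1, tolerance = 1e-9)
})

test_that("expected chi-square weight of null deviates approaches 1/2", {
  set.seed(202)
  w <- replicate(200, chi2Weight(abs(rnorm(1000))))
  expect_equal(mean(w), 0.5, tolerance = 0.05)
})

test_that("wE floor is the mean LJ term: -1 for ideal packing", {
  # two nonbonded waters exactly at their optimal separation
  w2 <- ensembleModel(
    data.frame(name = "O", resname = "HOH", chain = "W", resno = 1:2,
               ins = "", alt = "", occ = 1, b = 20,
               x = c(0, 3.04), y = 0, z = 0, element = "O"),
    library = aminoLibrary())
  s <- weScore(w2, library = aminoLibrary())
  expect_equal(meanLJ(s), -1, tolerance = 1e-9)
  expect_equal(wE(s), -1, tolerance = 1e-9)
})

test_that("wE aggregates categories exactly as the printed formula", {
  lib <- chainLibrary()
  m <- chainModel(d12 = 1.5 + 6 * 0.02)    # one 6-sigma bond
  r <- buildRestraints(m, lib)
  s <- weScore(m, r)
  devs <- categoryDeviates(m, r)
  hand <- 0
  for (cat in names(devs)) {
    d <- devs[[cat]]
    if (!length(d)) next
    hand <- hand + chi2Weight(d) * mean(d^2) +
      softPnn(max(d), length(d)) * clipEnergy(max(d)^2)
  }
  lj <- as.numeric(ljEnergies(m, r))
  hand <- hand + (if (length(lj)) mean(lj) else 0)
  expect_equal(wE(s), hand, tolerance = 1e-12)
  # the 6-sigma bond dominates through its clipped worst energy
  rep <- categoryReports(s)
  bond <- rep[rep$category == "bond", ]
  expect_equal(bond$clippedWorst, clipEnergy(36), tolerance = 1e-6)
  expect_gt(bond$wWorst, 0.99)
})

test_that("wE magnitude is ~10x the number of severely-outlying categories", {
  fx <- beadFixture("none", seed = 1)
  tr <- fx$truth
  # push one bond into a severe (8 sigma) outlier along its own axis
  a <- atoms(tr)
  cb <- which(a$name == "CB" & a$resno == 3 & a$alt == "A")
  ca <- which(a$name == "CA" & a$resno == 3 & a$alt == "A")
  dir <- c(a$x[cb] - a$x[ca], a$y[cb] - a$y[ca], a$z[cb] - a$z[ca])
  dir <- dir / sqrt(sum(dir^2))
  a[cb, c("x", "y", "z")] <- a[cb, c("x", "y", "z")] + 8 * 0.02 * dir
  m <- ensembleModel(a, library = beadLibrary())
  devs <- categoryDeviates(m, library = beadLibrary())
  expect_gte(max(devs$bond), 7)
  k <- sum(vapply(devs, function(d) length(d) && max(d) >= 6, TRUE))
  s <- wE(weScore(m, library = beadLibrary()))
  expect_gte(s, 5 * k)
  expect_lte(s, 20 * k)
})

test_that("wE is monotone in single-deviate improvements and gauge-invariant", {
  lib <- chainLibrary()
  w <- vapply(c(6, 5, 4, 2, 0.5),
              function(d) wE(weScore(chainModel(d12 = 1.5 + d * 0.02),
                                     library = lib)), 0)
  expect_true(all(diff(w) <= 1e-12))
  fx <- beadFixture("single_swap", seed = 1)
  expect_equal(wE(weScore(fx$tangled, library = beadLibrary())),
               wE(weScore(flipAllLetters(fx$tangled),
                          library = beadLibrary())),
               tolerance = 1e-9)
})
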