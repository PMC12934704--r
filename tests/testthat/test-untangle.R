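test_that("the swap scan is a fixed point on untangled models", {
  fx <- beadFixture("none", seed = 3)
  sc <- swapScan(fx$tangled, fx$target, library = beadLibrary())
  expect_equal(sum(moves(sc$ledger)$accepted), 0)
  expect_equal(assignmentMatch(sc$model, fx$truth)$percentMatch, 100)
})

test_that("the swap scan recovers planted single swaps", {
  for (sd in 1:3) {
    fx <- beadFixture("single_swap", seed = sd)
    sc <- swapScan(fx$tangled, fx$target, library = beadLibrary(),
                   maxMoves = 50)
    expect_equal(assignmentMatch(sc$model, fx$truth)$percentMatch, 100,
                 info = paste("seed", sd))
    acc <- moves(sc$ledger)
    expect_true(fx$planted %in% acc$move[acc$accepted])
  }
})

test_that("pair scans honor the move budget and never worsen wE", {
  fx <- beadFixture("single_swap", seed = 1)
  sc <- swapScan(fx$tangled, fx$target, arity = 2,
                 library = beadLibrary(), maxMoves = 5)
  expect_true(sc$budgetExhausted)
  expect_lte(nrow(moves(sc$ledger)), 5)
  w0 <- wE(weScore(localRefine(fx$tangled, fx$target,
                               library = beadLibrary()),
                   library = beadLibrary()))
  w1 <- wE(weScore(sc$model, library = beadLibrary()))
  expect_lte(w1, w0 + 1e-9)
})

test_that("rectified annealing is a one-way valve that lowers wE", {
  fx <- beadFixture("random_swaps", seed = 4)
  w0 <- wE(weScore(localRefine(fx$tangled, fx$target,
                               library = beadLibrary()),
                   library = beadLibrary()))
  rs <- rectifiedSA(fx$tangled, fx$target,
                    temps = c(2000, 3500, 5000, 6500, 8000),
                    seeds = 1:3, library = beadLibrary())
  m <- moves(rs$ledger)
  # accepted sweeps strictly improve; rejected sweeps are reverted, so
  # the running state never worsens
  expect_true(all(m$wEAfter[m$accepted] < m$wEBefore[m$accepted]))
  expect_true(all(diff(m$wEBefore) <= 1e-9))
  w1 <- wE(weScore(rs$model, library = beadLibrary()))
  expect_lte(w1, w0 + 1e-9)
  expect_lt(w1, w0)                 # this fixture does improve
  # some planted swaps are physically resolved
  am <- assignmentMatch(rs$model, fx$truth)$perGroup
  am0 <- assignmentMatch(fx$tangled, fx$truth)$perGroup
  resolved <- sum(am$sameAsReference[am$key %in% fx$planted])
  resolved0 <- sum(am0$sameAsReference[am0$key %in% fx$planted])
  expect_gt(resolved, resolved0)
})

test_that("rectified annealing leaves an already-optimal model unchanged", {
  fx <- beadFixture("none", seed = 2)
  base <- localRefine(fx$truth, fx$target, library = beadLibrary())
  w0 <- wE(weScore(base, library = beadLibrary()))
  rs <- rectifiedSA(base, fx$target, temps = 4000, seeds = 1,
                    library = beadLibrary())
  w1 <- wE(weScore(rs$model, library = beadLibrary()))
  expect_lte(w1, w0 + 1e-9)        # the valve never lets wE rise
})

test_that("the pincer maneuver releases high-strain traps under its guard", {
  released <- 0
  for (sd in 1:3) {
    fx <- beadFixture("single_swap", seed = sd)
    pr <- pincer(fx$tangled, fx$target, groups = fx$planted,
                 library = beadLibrary())
    m <- moves(pr$ledger)
    expect_true(all(m$wEAfter[m$accepted] < m$wEBefore[m$accepted]))
    w1 <- wE(weScore(pr$model, library = beadLibrary()))
    if (w1 - fx$wETruth < 0.1 * (fx$wETangled - fx$wETruth))
      released <- released + 1
  }
  expect_gte(released, 2)
  # pinching an effectively coincident pair is a no-op up to noise
  fx <- beadFixture("none", seed = 2)
  sg <- splitGroups(fx$truth)
  a <- atoms(fx$truth)
  sep <- vapply(sg$key, function(k) {
    s <- groupSites(fx$truth, k)
    sqrt(sum((coords(fx$truth)[s[1], ] - coords(fx$truth)[s[2], ])^2))
  }, 0)
  nearKey <- sg$key[which.min(sep)]
  w0 <- wE(weScore(localRefine(fx$truth, fx$target,
                               library = beadLibrary()),
                   library = beadLibrary()))
  pr <- pincer(fx$truth, fx$target, groups = nearKey,
               library = beadLibrary())
  w1 <- wE(weScore(pr$model, library = beadLibrary()))
  expect_lt(abs(w1 - w0), 0.05 * max(1, abs(w0)))
})

test_that("block-swap search recovers planted residue blocks", {
  fx <- beadFixture("block_swap", seed = 1, window = 3)
  bs <- blockSwapSearch(fx$tangled, fx$target, library = beadLibrary(),
                        maxMoves = 45)
  expect_equal(assignmentMatch(bs$model, fx$truth)$percentMatch, 100)
  # no accepted windows on an untangled fixture
  fx0 <- beadFixture("none", seed = 3)
  bs0 <- blockSwapSearch(fx0$tangled, fx0$target, library = beadLibrary(),
                         maxMoves = 30)
  expect_equal(sum(moves(bs0$ledger)$accepted), 0)
})

test_that("single-residue windows recover single-residue blocks", {
  fx <- beadFixture("block_swap", seed = 2, window = 1)
  bs <- blockSwapSearch(fx$tangled, fx$target, maxUnion = 1,
                        library = beadLibrary(), maxMoves = 20)
  expect_equal(assignmentMatch(bs$model, fx$truth)$percentMatch, 100)
})

test_that("cognate/non-cognate bond scores flag tangles locally", {
  lib <- beadLibrary()
  fx <- beadFixture("single_swap", seed = 1)
  # the ground truth carries no flags
  expect_equal(sum(tangleReport(fx$truth, lib)$flagged), 0)
  # flags cluster at the planted swap (same or bonded residue)
  rep <- tangleReport(fx$tangled, lib)
  expect_gt(sum(rep$flagged), 0)
  plantedRes <- as.integer(sub("^A\\|([0-9]+)\\|.*$", "\\1", fx$planted))
  flaggedRes <- unique(as.integer(sub("^A\\|([0-9]+)\\|.*$", "\\1",
                                      c(rep$key1[rep$flagged],
                                        rep$key2[rep$flagged]))))
  expect_true(all(abs(flaggedRes - plantedRes) <= 1))
  # flags are invariant under global letter exchange
  repFlip <- tangleReport(flipAllLetters(fx$tangled), lib)
  expect_identical(rep$flagged, repFlip$flagged)
  # refining with a high density weight enhances the score contrast
  hi <- localRefine(fx$tangled, fx$target,
                    config = refineConfig(wx = 100), library = lib)
  gap <- function(r) max(pmax(r$AA, r$BB) - pmin(r$AB, r$BA))
  expect_gt(gap(tangleReport(hi, lib)), gap(rep))
})
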