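#' @include refine.R
NULL

emptyLedger <- function() {
  new("UntangleLedger", moves = data.frame(
    move = character(0), wEBefore = numeric(0), wEAfter = numeric(0),
    densBefore = numeric(0), densAfter = numeric(0),
    accepted = logical(0), stringsAsFactors = FALSE))
}

recordMove <- function(ledger, move, wEBefore, wEAfter, densBefore,
                       densAfter, accepted) {
  ledger@moves <- rbind(ledger@moves, data.frame(
    move = move, wEBefore = wEBefore, wEAfter = wEAfter,
    densBefore = densBefore, densAfter = densAfter, accepted = accepted,
    stringsAsFactors = FALSE))
  ledger
}

# Score state used by the acceptance guard of every maneuver.
scoreState <- function(model, target, config, library) {
  restr <- buildRestraints(model, library)
  list(model = model, restr = restr,
       wE = wE(weScore(model, restr)),
       dens = as.numeric(densityMisfit(model, target,
                                       scale = config$densityScale,
                                       bBase = config$bBase,
                                       wantGrad = FALSE)))
}

# Refine the input once, but keep the raw input if refinement does not
# improve wE (the input may already be a refined state whose wE the
# total-energy minimizer would otherwise nudge upward), so every
# maneuver's output wE never exceeds its input wE.
initialState <- function(model, target, config, library) {
  s0 <- scoreState(model, target, config, library)
  s1 <- scoreState(localRefine(model, target, s0$restr, config, library),
                   target, config, library)
  if (s1$wE < s0$wE) s1 else s0
}

# Candidate split groups ordered by decreasing strain (max per-site
# energy of the group's members), ties broken by atom key.
orderCandidates <- function(state, model) {
  sg <- splitGroups(model)
  if (!nrow(sg)) return(character(0))
  pae <- perAtomEnergy(model, state$restr)
  akey <- atomKeys(model)
  strain <- vapply(sg$key, function(k)
    max(pae[akey == k & model@atoms$alt != ""]), 0)
  sg$key[order(-strain, sg$key)]
}

#' Swap-and-rerefine scan
#'
#' For each candidate split group (or pair of groups when \code{arity} is
#' 2), trial-swaps its conformer letters, re-refines the whole structure
#' and scores it. Within each sweep every candidate is evaluated from the
#' current model (in order of decreasing strain) and the best strictly
#' wE-decreasing move is accepted; all other trials are reverted. Sweeps
#' repeat until no move improves wE or the move budget is exhausted. The
#' result's wE never exceeds the input's.
#'
#' @param model an \linkS4class{EnsembleModel} (refined once internally
#'   before scanning).
#' @param target a \linkS4class{DensityGrid}.
#' @param candidates atom keys of the split groups to scan; default all.
#' @param arity 1 (single groups) or 2 (pairs of groups).
#' @param config a \code{\link{refineConfig}}.
#' @param library restraint library.
#' @param maxMoves move budget (attempted refinements).
#' @param minImprove smallest wE decrease counted as an improvement;
#'   the default ignores differences below the numerical reproducibility
#'   of the refinement.
#' @return list with \code{model}, \code{ledger} (an
#'   \linkS4class{UntangleLedger}) and \code{budgetExhausted}.
#' @export
swapScan <- function(model, target, candidates = NULL, arity = 1,
                     config = refineConfig(), library = NULL,
                     maxMoves = Inf, minImprove = 1e-5) {
  stopifnot(arity %in% c(1, 2))
  if (is.null(library)) library <- defaultLibrary(model)
  state <- initialState(model, target, config, library)
  ledger <- emptyLedger()
  tried <- 0
  exhausted <- FALSE
  repeat {
    keys <- candidates %||% orderCandidates(state, state$model)
    if (!is.null(candidates))
      keys <- intersect(orderCandidates(state, state$model), candidates)
    movesList <- if (arity == 1) as.list(keys) else {
      if (length(keys) < 2) list() else
        combn(keys, 2, simplify = FALSE)
    }
    best <- NULL
    rows <- integer(0)
    for (mv in movesList) {
      if (tried >= maxMoves) { exhausted <- TRUE; break }
      tried <- tried + 1
      trial <- applySwaps(state$model, swapSet(mv))
      trial <- localRefine(trial, target, config = config,
                           library = library)
      tstate <- scoreState(trial, target, config, library)
      ledger <- recordMove(ledger, paste(mv, collapse = " + "),
                           state$wE, tstate$wE, state$dens, tstate$dens,
                           FALSE)
      rows <- c(rows, nrow(ledger@moves))
      if (tstate$wE < state$wE - minImprove &&
          (is.null(best) || tstate$wE < best$state$wE))
        best <- list(state = tstate, row = nrow(ledger@moves))
    }
    if (!is.null(best)) {
      ledger@moves$accepted[best$row] <- TRUE
      state <- best$state
    }
    if (is.null(best) || exhausted) break
  }
  list(model = state$model, ledger = ledger, budgetExhausted = exhausted)
}

#' Rectified simulated annealing
#'
#' For each (temperature, seed) sweep the coordinates receive Gaussian
#' kicks with scale proportional to the square root of the temperature and
#' the structure is re-refined. Atoms whose per-atom statistical energy
#' worsened by more than \code{worseThreshold} are restored to their
#' pre-kick positions and the structure re-refined again. The sweep's
#' outcome is kept only if wE decreased (the one-way-valve), so the final
#' wE never exceeds the input's.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param target a \linkS4class{DensityGrid}.
#' @param temps annealing temperatures, Kelvin-like units.
#' @param seeds integer seeds, one annealing run per (temp, seed).
#' @param worseThreshold per-atom energy increase beyond which an atom is
#'   restored (default 4, a 2-sigma-equivalent).
#' @param kickScale Angstrom of kick per sqrt(temperature unit).
#' @param config a \code{\link{refineConfig}}.
#' @param library restraint library.
#' @param minImprove smallest wE decrease counted as an improvement.
#' @return list with \code{model} and \code{ledger}.
#' @export
rectifiedSA <- function(model, target, temps = c(2000, 4000, 8000),
                        seeds = 1:2, worseThreshold = 4,
                        kickScale = 0.012, config = refineConfig(),
                        library = NULL, minImprove = 1e-5) {
  if (is.null(library)) library <- defaultLibrary(model)
  state <- initialState(model, target, config, library)
  ledger <- emptyLedger()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (sd0 in seeds) for (temp in temps) {
    set.seed(as.integer((config$seed + 131071 * sd0 + round(temp)) %%
                          .Machine$integer.max))
    X0 <- coords(state$model)
    kick <- matrix(rnorm(length(X0), sd = kickScale * sqrt(temp)),
                   nrow = nrow(X0))
    trial <- state$model
    coords(trial) <- X0 + kick
    trial <- localRefine(trial, target, state$restr, config, library)
    pae0 <- perAtomEnergy(state$model, state$restr)
    pae1 <- perAtomEnergy(trial, state$restr)
    worse <- which(pae1 - pae0 > worseThreshold)
    if (length(worse)) {
      Xr <- coords(trial)
      Xr[worse, ] <- X0[worse, ]
      coords(trial) <- Xr
      trial <- localRefine(trial, target, state$restr, config, library)
    }
    tstate <- scoreState(trial, target, config, library)
    accept <- tstate$wE < state$wE - minImprove
    ledger <- recordMove(ledger, sprintf("rsa T=%g seed=%d", temp, sd0),
                         state$wE, tstate$wE, state$dens, tstate$dens,
                         accept)
    if (accept) state <- tstate
  }
  list(model = state$model, ledger = ledger)
}

#' The pincer maneuver
#'
#' Each listed split group's members are moved to their mutual midpoint
#' (the top of the density-misfit hill) and harmonically restrained there
#' while the rest of the structure relaxes; the restraints are then
#' released and the structure re-refined, giving the geometry term the
#' maximum chance of pulling each member down the correct side of the
#' density. A group's maneuver is accepted only if wE decreases.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param target a \linkS4class{DensityGrid}.
#' @param groups atom keys of split groups to pinch; default all, ordered
#'   by decreasing strain.
#' @param config a \code{\link{refineConfig}}.
#' @param anchorK force constant of the midpoint restraint.
#' @param library restraint library.
#' @param minImprove smallest wE decrease counted as an improvement.
#' @return list with \code{model} and \code{ledger}.
#' @export
pincer <- function(model, target, groups = NULL, config = refineConfig(),
                   anchorK = 50, library = NULL, minImprove = 1e-5) {
  if (is.null(library)) library <- defaultLibrary(model)
  state <- initialState(model, target, config, library)
  ledger <- emptyLedger()
  groups <- groups %||% orderCandidates(state, state$model)
  for (g in groups) {
    sites <- groupSites(state$model, g)
    X <- coords(state$model)
    mid <- unname(colMeans(X[sites, , drop = FALSE]))
    trial <- state$model
    Xt <- X
    Xt[sites, ] <- matrix(mid, length(sites), 3, byrow = TRUE)
    coords(trial) <- Xt
    cfgA <- config
    cfgA$restrainedSites <- data.frame(site = unname(sites), x = mid[1],
                                       y = mid[2], z = mid[3], k = anchorK)
    trial <- localRefine(trial, target, state$restr, cfgA, library)
    trial <- localRefine(trial, target, state$restr, config, library)
    tstate <- scoreState(trial, target, config, library)
    accept <- tstate$wE < state$wE - minImprove
    ledger <- recordMove(ledger, paste("pincer", g), state$wE, tstate$wE,
                         state$dens, tstate$dens, accept)
    if (accept) state <- tstate
  }
  list(model = state$model, ledger = ledger)
}

#' Block-swap search over contiguous residue windows
#'
#' Trial-swaps all split groups inside each window (and unions of adjacent
#' windows), re-refines, and accepts a window only if wE strictly
#' decreases. Long-range traps — large regions with their conformer
#' assignments flipped relative to the ground truth but little localized
#' strain — cannot be released one atom at a time; flipping the whole
#' block at once can.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param target a \linkS4class{DensityGrid}.
#' @param windows list of character vectors of residue keys; default one
#'   window per residue.
#' @param maxUnion maximum number of adjacent windows merged into one
#'   trial block (default all).
#' @param config a \code{\link{refineConfig}}.
#' @param library restraint library.
#' @param maxMoves move budget.
#' @param minImprove smallest wE decrease counted as an improvement.
#' @return list with \code{model}, \code{ledger}, \code{budgetExhausted}.
#' @export
blockSwapSearch <- function(model, target, windows = NULL,
                            maxUnion = NULL, config = refineConfig(),
                            library = NULL, maxMoves = Inf,
                            minImprove = 1e-5) {
  if (is.null(library)) library <- defaultLibrary(model)
  if (is.null(windows)) {
    rk <- unique(residueKeys(model))
    windows <- as.list(rk)
  }
  maxUnion <- maxUnion %||% length(windows)
  state <- initialState(model, target, config, library)
  ledger <- emptyLedger()
  sg <- splitGroups(state$model)
  groupRes <- sub("\\|[^|]+$", "", sg$key)
  tried <- 0
  exhausted <- FALSE
  repeat {
    improved <- FALSE
    for (size in seq_len(maxUnion)) {
      for (start in seq_len(length(windows) - size + 1)) {
        if (tried >= maxMoves) { exhausted <- TRUE; break }
        resSet <- unique(unlist(windows[start:(start + size - 1)]))
        keys <- sg$key[groupRes %in% resSet]
        if (!length(keys)) next
        tried <- tried + 1
        trial <- applySwaps(state$model, swapSet(list(keys)))
        trial <- localRefine(trial, target, config = config,
                             library = library)
        tstate <- scoreState(trial, target, config, library)
        accept <- tstate$wE < state$wE - minImprove
        ledger <- recordMove(
          ledger, sprintf("block[%d+%d]", start, size - 1),
          state$wE, tstate$wE, state$dens, tstate$dens, accept)
        if (accept) { state <- tstate; improved <- TRUE }
      }
      if (exhausted) break
    }
    if (!improved || exhausted) break
  }
  list(model = state$model, ledger = ledger, budgetExhausted = exhausted)
}

#' Cognate/non-cognate bond scoring (tangle report)
#'
#' For every covalent bond whose two end atoms are both split, evaluates
#' the statistical bond-length energy of the two cognate pairings (AA, BB)
#' and the two non-cognate pairings (AB, BA). A bond is flagged when its
#' best non-cognate energy beats its worst cognate energy — the signature
#' of a tangled assignment. Flags are invariant under global letter
#' exchange.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param library restraint library (for ideal bond lengths).
#' @return data.frame with one row per doubly-split bond: \code{key1},
#'   \code{key2}, \code{AA}, \code{BB}, \code{AB}, \code{BA},
#'   \code{flagged}.
#' @export
tangleReport <- function(model, library = NULL) {
  if (is.null(library)) library <- defaultLibrary(model)
  sg <- splitGroups(model)
  b <- model@bonds
  a <- model@atoms
  akey <- atomKeys(model)
  X <- coords(model)
  nameOf <- function(k) sub("^.*\\|", "", k)
  out <- list()
  for (i in seq_len(nrow(b))) {
    k1 <- b$key1[i]; k2 <- b$key2[i]
    if (!(k1 %in% sg$key && k2 %in% sg$key)) next
    vs <- switch(b$kind[i],
      intra = libBondLookup(library,
                            sub("^.*\\|([^|]+)\\|[^|]+$", "\\1", k1),
                            nameOf(k1), nameOf(k2)),
      link = libLinkBondLookup(library, nameOf(k1), nameOf(k2)),
      ss = library$ssBond)
    if (is.null(vs)) next
    s1 <- groupSites(model, k1)
    s2 <- groupSites(model, k2)
    lets <- sort(intersect(names(s1), names(s2)))
    if (length(lets) != 2) next
    bondE <- function(sa, sb) {
      r <- sqrt(sum((X[sa, ] - X[sb, ])^2))
      ((r - vs["v0"]) / vs["sigma"])^2
    }
    AA <- bondE(s1[lets[1]], s2[lets[1]])
    BB <- bondE(s1[lets[2]], s2[lets[2]])
    AB <- bondE(s1[lets[1]], s2[lets[2]])
    BA <- bondE(s1[lets[2]], s2[lets[1]])
    out[[length(out) + 1]] <- data.frame(
      key1 = k1, key2 = k2, AA = unname(AA), BB = unname(BB),
      AB = unname(AB), BA = unname(BA),
      flagged = min(AB, BA) < max(AA, BB),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(key1 = character(0), key2 = character(0),
                      AA = numeric(0), BB = numeric(0), AB = numeric(0),
                      BA = numeric(0), flagged = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
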