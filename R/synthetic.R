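#' @include untangle.R
NULL

#' Specification of a synthetic two-conformer fixture
#'
#' The generator builds a bead-peptide chain (backbone analog N, CA, C
#' plus one side-chain bead CB per residue) with exact library geometry,
#' then displaces each residue's atoms perpendicular to the chain plane by
#' a smooth two-lobe amplitude profile: conformer A at +u, conformer B at
#' -u, every atom split at occupancy 0.5. The "correlated" (windshield
#' wiper) and "anti" (jumping jacks; displacement sign flipped beyond the
#' low-amplitude hinge) modes produce identical position sets — hence
#' identical density — but different ground-truth assignments.
#'
#' @param nResidues chain length (>= 2).
#' @param mode \code{"correlated"} or \code{"anti"}.
#' @param splitAmplitude peak A-to-B separation, Angstrom.
#' @param tangleMode \code{"none"}, \code{"single_swap"},
#'   \code{"random_swaps"} or \code{"block_swap"}.
#' @param fraction fraction of split groups swapped for
#'   \code{"random_swaps"} (in (0, 1)).
#' @param window block length in residues for \code{"block_swap"}, or a
#'   vector of residue indices; \code{NULL} flips everything beyond the
#'   hinge (the low-strain long-range trap).
#' @param noiseSD density noise as a fraction of the peak density.
#' @param seed integer seed controlling every random choice.
#' @param spacing target grid spacing, Angstrom.
#' @return a list of class \code{fixtureSpec}.
#' @export
fixtureSpec <- function(nResidues = 10, mode = c("correlated", "anti"),
                        splitAmplitude = 0.7,
                        tangleMode = c("none", "single_swap",
                                       "random_swaps", "block_swap"),
                        fraction = 0.25, window = 3, noiseSD = 0.002,
                        seed = 1L, spacing = 0.3) {
  mode <- match.arg(mode)
  tangleMode <- match.arg(tangleMode)
  stopifnot(nResidues >= 2, splitAmplitude > 0,
            fraction > 0, fraction < 1, noiseSD >= 0)
  structure(list(nResidues = as.integer(nResidues), mode = mode,
                 splitAmplitude = splitAmplitude, tangleMode = tangleMode,
                 fraction = fraction, window = window, noiseSD = noiseSD,
                 seed = as.integer(seed), spacing = spacing),
            class = "fixtureSpec")
}

#' @export
print.fixtureSpec <- function(x, ...) {
  cat(sprintf(
    "fixtureSpec: %d residues, %s mode, amplitude %.2f A, tangle %s, seed %d\n",
    x$nResidues, x$mode, x$splitAmplitude, x$tangleMode, x$seed))
  invisible(x)
}

# NeRF placement: position D bonded to C, with bond length b, angle
# B-C-D (deg) and torsion A-B-C-D (deg).
nerfPlace <- function(A, B, C, b, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-b * cos(th), b * sin(th) * cos(ph), b * sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Ideal extended bead chain (one conformer), exact library geometry.
buildBeadChain <- function(n) {
  pos <- matrix(NA_real_, 4 * n, 3)
  nm <- character(4 * n); resno <- integer(4 * n)
  row <- function(i, what) (i - 1) * 4 + match(what, c("N", "CA", "C", "CB"))
  pos[row(1, "N"), ] <- c(0, 0, 0)
  pos[row(1, "CA"), ] <- c(1.46, 0, 0)
  th <- 110 * pi / 180
  pos[row(1, "C"), ] <- pos[row(1, "CA"), ] +
    1.52 * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    N <- pos[row(i, "N"), ]; CA <- pos[row(i, "CA"), ]
    C <- pos[row(i, "C"), ]
    chi <- if (i %% 2 == 1) 120 else -120
    pos[row(i, "CB"), ] <- nerfPlace(C, N, CA, 1.53, 110, chi)
    if (i < n) {
      Np <- nerfPlace(N, CA, C, 1.33, 116, 180)
      CAp <- nerfPlace(CA, C, Np, 1.46, 122, 180)
      Cp <- nerfPlace(C, Np, CAp, 1.52, 110, 180)
      pos[row(i + 1, "N"), ] <- Np
      pos[row(i + 1, "CA"), ] <- CAp
      pos[row(i + 1, "C"), ] <- Cp
    }
    nm[(i - 1) * 4 + 1:4] <- c("N", "CA", "C", "CB")
    resno[(i - 1) * 4 + 1:4] <- i
  }
  list(pos = pos, name = nm, resno = resno)
}

# Two-lobe displacement magnitude profile and the hinge residue index.
displacementProfile <- function(n, amplitude) {
  i <- seq_len(n)
  m <- (amplitude / 2) * abs(sin(2 * pi * (i - 0.7) / n))
  hinge <- floor(0.7 + n / 2) + 1
  list(m = m, hinge = min(hinge, n))
}

# Ground-truth two-conformer bead ensemble for a spec.
buildTruth <- function(spec) {
  n <- spec$nResidues
  ch <- buildBeadChain(n)
  prof <- displacementProfile(n, spec$splitAmplitude)
  sign <- rep(1, n)
  if (spec$mode == "anti") sign[prof$hinge:n] <- -1
  rows <- list()
  for (i in seq_len(n)) {
    u <- sign[i] * prof$m[i]
    sel <- which(ch$resno == i)
    for (alt in c("A", "B")) {
      z <- if (alt == "A") u else -u
      rows[[length(rows) + 1]] <- data.frame(
        name = ch$name[sel], resname = "BEA", chain = "A",
        resno = i, ins = "", alt = alt, occ = 0.5, b = 10,
        x = ch$pos[sel, 1], y = ch$pos[sel, 2],
        z = ch$pos[sel, 3] + z,
        element = c(N = "N", CA = "C", C = "C", CB = "C")[ch$name[sel]],
        stringsAsFactors = FALSE)
    }
  }
  ensembleModel(do.call(rbind, rows), library = beadLibrary())
}

# Planted swap set for a spec's tangle mode (seeded choices).
plantedSwaps <- function(spec, truth) {
  sg <- splitGroups(truth)
  keyRes <- as.integer(sub("^A\\|([0-9]+)\\|.*$", "\\1", sg$key))
  keyName <- sub("^.*\\|", "", sg$key)
  prof <- displacementProfile(spec$nResidues, spec$splitAmplitude)
  set.seed(spec$seed)
  keys <- switch(spec$tangleMode,
    none = character(0),
    single_swap = {
      # a CB at a high-amplitude residue: the high-strain localized trap
      cand <- which(keyName == "CB" &
                      prof$m[keyRes] >= 0.8 * max(prof$m))
      sg$key[sample(cand, 1)]
    },
    random_swaps = {
      k <- max(2, round(spec$fraction * nrow(sg)))
      sg$key[sample(nrow(sg), k)]
    },
    block_swap = {
      res <- if (is.null(spec$window)) {
        prof$hinge:spec$nResidues
      } else if (length(spec$window) > 1) {
        spec$window
      } else {
        w <- min(spec$window, spec$nResidues - 1)
        start <- sample(spec$nResidues - w + 1, 1)
        start:(start + w - 1)
      }
      sg$key[keyRes %in% res]
    })
  keys
}

#' Generate a ground-truth ensemble, target density and tangled model
#'
#' The ground truth satisfies every bonded restraint to within one sigma
#' in both conformers and has no Lennard-Jones pair above 0.5. The target
#' density is synthesized from the ground truth with seeded band-limited
#' noise. The tangled model applies the planted swaps and is then locally
#' refined; it is only emitted if it sits in a genuine trap (its refined
#' wE strictly exceeds the ground truth's), otherwise the seed is advanced
#' and generation retried a bounded number of times.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param config a \code{\link{refineConfig}} used for the trap gate.
#' @param maxRetry bound on regeneration attempts.
#' @return list with \code{truth}, \code{target}, \code{tangled},
#'   \code{planted} (atom keys of the planted swap), \code{spec} and
#'   \code{wETruth}, \code{wETangled}.
#' @export
makeToyEnsemble <- function(spec, config = refineConfig(),
                            maxRetry = 5) {
  lib <- beadLibrary()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (attempt in seq_len(maxRetry)) {
    sp <- spec
    sp$seed <- spec$seed + 1000L * (attempt - 1L)
    truth <- buildTruth(sp)
    restr <- buildRestraints(truth, lib)
    dv <- suppressWarnings(termDeviates(truth, restr))
    maxDev <- max(abs(c(dv$bond, dv$angle, dv$torsion)), na.rm = TRUE)
    lj <- as.numeric(ljEnergies(truth, restr))
    if (maxDev > 1 || (length(lj) && max(lj) > 0.5)) next
    grid <- gridFromModel(truth, spacing = sp$spacing)
    target <- synthesizeDensity(truth, grid, bBase = config$bBase)
    if (sp$noiseSD > 0)
      target <- addDensityNoise(target,
                                sd = sp$noiseSD * max(target@values),
                                seed = sp$seed + 7L)
    wTruth <- wE(weScore(truth, restr))
    planted <- plantedSwaps(sp, truth)
    if (sp$tangleMode == "none") {
      return(list(truth = truth, target = target, tangled = truth,
                  planted = character(0), spec = sp, wETruth = wTruth,
                  wETangled = wTruth))
    }
    tangled <- applySwaps(truth, swapSet(list(planted)))
    tangled <- localRefine(tangled, target, config = config,
                           library = lib)
    wTangled <- wE(weScore(tangled, library = lib))
    if (wTangled > wTruth) {
      return(list(truth = truth, target = target, tangled = tangled,
                  planted = planted, spec = sp, wETruth = wTruth,
                  wETangled = wTangled))
    }
  }
  stopf("could not generate a genuinely trapped fixture in %d attempts",
        maxRetry)
}

#' Energy profile along a split-group exchange path
#'
#' Linearly interpolates the two members of one split group through their
#' exchange (lambda = 0 current assignment, 0.5 coincident, 1 swapped),
#' relaxing nothing else, and records the density misfit and total
#' geometry (bonded + LJ) energy at each step. The density misfit is
#' symmetric about the midpoint and maximal near it: the
#' density-misfit barrier.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param group atom key of a split group with exactly two members.
#' @param target a \linkS4class{DensityGrid}.
#' @param nSteps number of lambda values.
#' @param config a \code{\link{refineConfig}} (density scale and bBase).
#' @param library restraint library.
#' @return data.frame with columns \code{lambda}, \code{Edens},
#'   \code{Egeom}.
#' @export
barrierProfile <- function(model, group, target, nSteps = 21,
                           config = refineConfig(), library = NULL) {
  if (is.null(library)) library <- defaultLibrary(model)
  sites <- groupSites(model, group)
  if (length(sites) != 2)
    stopf("barrier profile needs a 2-member group; '%s' has %d",
          group, length(sites))
  restr <- buildRestraints(model, library)
  X0 <- coords(model)
  pA <- X0[sites[1], ]; pB <- X0[sites[2], ]
  lambdas <- seq(0, 1, length.out = nSteps)
  out <- data.frame(lambda = lambdas, Edens = NA_real_, Egeom = NA_real_)
  for (r in seq_along(lambdas)) {
    l <- lambdas[r]
    X <- X0
    X[sites[1], ] <- (1 - l) * pA + l * pB
    X[sites[2], ] <- (1 - l) * pB + l * pA
    e <- totalEnergy(X, model, target, restr, config, wantGrad = FALSE)
    out$Edens[r] <- unname(e$parts["density"]) / config$wx
    out$Egeom[r] <- e$total - unname(e$parts["density"])
  }
  out
}
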