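#' @include density.R
NULL

#' Refinement configuration
#'
#' @param wx density-term weight (dimensionless, > 0), the real-space
#'   analog of a refinement program's X-ray/geometry weight.
#' @param maxIter maximum accepted minimizer iterations.
#' @param tol convergence threshold on the decrease of the total energy.
#' @param densityScale scale of the normalized density misfit (see
#'   \code{\link{densityMisfit}}).
#' @param bBase baseline B factor for density synthesis, Angstrom^2.
#' @param restrainedSites optional data.frame \code{site}, \code{x},
#'   \code{y}, \code{z}, \code{k}: harmonic positional anchors with force
#'   constant k (energy k * |p - anchor|^2).
#' @param seed integer seed recorded with the run (the minimizer itself is
#'   deterministic).
#' @return a list of class \code{refineConfig}.
#' @export
refineConfig <- function(wx = 1, maxIter = 150, tol = 1e-4,
                         densityScale = 2e6, bBase = 10,
                         restrainedSites = NULL, seed = 1L) {
  stopifnot(wx > 0, tol > 0, maxIter >= 1)
  structure(list(wx = wx, maxIter = as.integer(maxIter), tol = tol,
                 densityScale = densityScale, bBase = bBase,
                 restrainedSites = restrainedSites,
                 seed = as.integer(seed)),
            class = "refineConfig")
}

#' @export
print.refineConfig <- function(x, ...) {
  cat(sprintf("refineConfig: wx=%g maxIter=%d tol=%g densityScale=%g\n",
              x$wx, x$maxIter, x$tol, x$densityScale))
  invisible(x)
}

# Cached total-energy evaluator: precomputes target vector, atom Gaussian
# parameters and restraint index matrices once, then evaluates
# T = wx * E_dens + E_geom + E_LJ (+ anchors) and its gradient from a bare
# coordinate matrix. The density difference of the last energy evaluation
# is reused for the gradient pass.
makeEnergyEvaluator <- function(model, target, restraints, config) {
  g <- atomGaussians(model, config$bBase)
  dims <- as.integer(dim(target@values))
  tv <- as.numeric(target@values)
  normt <- sum(tv^2)
  if (normt <= 0) stopf("target density is empty")
  r <- restraints
  bIdx <- if (nrow(r@bonds)) as.matrix(r@bonds[, c("i", "j")])
  aIdx <- if (nrow(r@angles)) as.matrix(r@angles[, c("i", "j", "k")])
  tIdx <- if (nrow(r@torsions)) as.matrix(r@torsions[, c("i", "j", "k", "l")])
  nIdx <- if (nrow(r@nonbond)) as.matrix(r@nonbond[, c("i", "j")])
  rs <- config$restrainedSites
  pref <- config$densityScale / normt
  env <- new.env(parent = emptyenv())

  energy <- function(X) {
    v <- cpp_density(X, g$amp, g$sig2, target@origin, target@spacing,
                     dims, g$cutoff)
    diff <- v - tv
    env$diff <- diff
    total <- config$wx * config$densityScale * sum(diff^2) / normt
    if (!is.null(bIdx))
      total <- total + sum(cpp_bond_terms(X, bIdx, r@bonds$v0,
                                          r@bonds$sigma, FALSE)$dev^2,
                           na.rm = TRUE)
    if (!is.null(aIdx))
      total <- total + sum(cpp_angle_terms(X, aIdx, r@angles$v0,
                                           r@angles$sigma, FALSE)$dev^2,
                           na.rm = TRUE)
    if (!is.null(tIdx))
      total <- total + sum(cpp_torsion_terms(X, tIdx, r@torsions$v0,
                                             r@torsions$sigma,
                                             r@torsions$period,
                                             FALSE)$dev^2, na.rm = TRUE)
    if (!is.null(nIdx))
      total <- total + sum(cpp_lj_terms(X, nIdx, r@nonbond$r0, FALSE)$e)
    if (!is.null(rs) && nrow(rs)) {
      dp <- X[rs$site, , drop = FALSE] - as.matrix(rs[, c("x", "y", "z")])
      total <- total + sum(rs$k * rowSums(dp^2))
    }
    total
  }

  gradient <- function(X) {
    # uses the density difference stashed by the last energy(X) call
    grad <- config$wx * cpp_density_grad(X, g$amp, g$sig2, target@origin,
                                         target@spacing, dims, env$diff,
                                         g$cutoff, pref)
    if (!is.null(bIdx))
      grad <- grad + cpp_bond_terms(X, bIdx, r@bonds$v0, r@bonds$sigma,
                                    TRUE)$grad
    if (!is.null(aIdx))
      grad <- grad + cpp_angle_terms(X, aIdx, r@angles$v0, r@angles$sigma,
                                     TRUE)$grad
    if (!is.null(tIdx))
      grad <- grad + cpp_torsion_terms(X, tIdx, r@torsions$v0,
                                       r@torsions$sigma, r@torsions$period,
                                       TRUE)$grad
    if (!is.null(nIdx))
      grad <- grad + cpp_lj_terms(X, nIdx, r@nonbond$r0, TRUE)$grad
    if (!is.null(rs) && nrow(rs)) {
      dp <- X[rs$site, , drop = FALSE] - as.matrix(rs[, c("x", "y", "z")])
      for (t in seq_len(nrow(rs)))
        grad[rs$site[t], ] <- grad[rs$site[t], ] + 2 * rs$k[t] * dp[t, ]
    }
    grad
  }
  list(energy = energy, gradient = gradient)
}

# Total energy T = wx * E_dens + sum E_geom + sum E_LJ (+ anchors), with
# gradient. Degenerate angle/torsion terms contribute nothing.
totalEnergy <- function(X, model, target, restraints, config,
                        wantGrad = TRUE) {
  n <- nrow(X)
  grad <- if (wantGrad) matrix(0, n, 3) else NULL
  r <- restraints

  model@atoms$x <- X[, 1]; model@atoms$y <- X[, 2]; model@atoms$z <- X[, 3]
  dens <- densityMisfit(model, target, scale = config$densityScale,
                        bBase = config$bBase, wantGrad = wantGrad)
  total <- config$wx * as.numeric(dens)
  parts <- c(density = config$wx * as.numeric(dens))
  if (wantGrad) grad <- grad + config$wx * attr(dens, "gradient")

  if (nrow(r@bonds)) {
    res <- cpp_bond_terms(X, as.matrix(r@bonds[, c("i", "j")]), r@bonds$v0,
                          r@bonds$sigma, wantGrad)
    parts["bond"] <- sum(res$dev^2, na.rm = TRUE)
    total <- total + parts["bond"]
    if (wantGrad) grad <- grad + res$grad
  }
  if (nrow(r@angles)) {
    res <- cpp_angle_terms(X, as.matrix(r@angles[, c("i", "j", "k")]),
                           r@angles$v0, r@angles$sigma, wantGrad)
    parts["angle"] <- sum(res$dev^2, na.rm = TRUE)
    total <- total + parts["angle"]
    if (wantGrad) grad <- grad + res$grad
  }
  if (nrow(r@torsions)) {
    res <- cpp_torsion_terms(X, as.matrix(r@torsions[, c("i", "j", "k", "l")]),
                             r@torsions$v0, r@torsions$sigma,
                             r@torsions$period, wantGrad)
    parts["torsion"] <- sum(res$dev^2, na.rm = TRUE)
    total <- total + parts["torsion"]
    if (wantGrad) grad <- grad + res$grad
  }
  if (nrow(r@nonbond)) {
    res <- cpp_lj_terms(X, as.matrix(r@nonbond[, c("i", "j")]),
                        r@nonbond$r0, wantGrad)
    parts["lj"] <- sum(res$e)
    total <- total + parts["lj"]
    if (wantGrad) grad <- grad + res$grad
  }
  rs <- config$restrainedSites
  if (!is.null(rs) && nrow(rs)) {
    dp <- X[rs$site, , drop = FALSE] - as.matrix(rs[, c("x", "y", "z")])
    parts["anchor"] <- sum(rs$k * rowSums(dp^2))
    total <- total + parts["anchor"]
    if (wantGrad)
      for (t in seq_len(nrow(rs)))
        grad[rs$site[t], ] <- grad[rs$site[t], ] + 2 * rs$k[t] * dp[t, ]
  }
  list(total = as.numeric(total), parts = parts, grad = grad)
}

#' Local real-space refinement of coordinates
#'
#' Minimizes the total energy T = wx * E_dens + E_geometry + E_LJ over all
#' atomic coordinates with fixed conformer assignments, occupancies and B
#' factors, using a monotone, deterministic gradient descent
#' (Barzilai-Borwein step length with Armijo backtracking): T is
#' non-increasing over accepted iterations and identical inputs give
#' bit-identical output coordinates. Returns when the energy decrease
#' drops below \code{tol} or after \code{maxIter} accepted steps.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param target a \linkS4class{DensityGrid}.
#' @param restraints optional prebuilt \linkS4class{RestraintSet}.
#' @param config a \code{\link{refineConfig}}.
#' @param library restraint library used when \code{restraints} is
#'   missing.
#' @return the refined model, with attributes \code{trajectory} (accepted
#'   total energies) and \code{converged}.
#' @export
localRefine <- function(model, target, restraints = NULL,
                        config = refineConfig(), library = NULL) {
  if (is.null(restraints)) restraints <- buildRestraints(model, library)
  ev <- makeEnergyEvaluator(model, target, restraints, config)
  X <- coords(model)
  e0 <- ev$energy(X)
  if (!is.finite(e0)) {
    parts <- totalEnergy(X, model, target, restraints, config,
                         wantGrad = FALSE)$parts
    stopf("non-finite starting energy in term(s): %s",
          paste(names(parts)[!is.finite(parts)], collapse = ", "))
  }
  G <- ev$gradient(X)
  traj <- e0
  gn <- max(abs(G))
  s <- if (gn > 0) 0.001 / gn else 0
  converged <- FALSE
  iter <- 0
  while (iter < config$maxIter && s > 0) {
    iter <- iter + 1
    g2 <- sum(G^2)
    accepted <- FALSE
    st <- s
    for (bt in 1:40) {
      X1 <- X - st * G
      e1 <- ev$energy(X1)
      if (is.finite(e1) && e1 <= e0 - 1e-4 * st * g2) {
        accepted <- TRUE
        break
      }
      st <- st / 2
    }
    if (!accepted) { converged <- TRUE; break }
    G1 <- ev$gradient(X1)
    dX <- X1 - X
    dG <- G1 - G
    denom <- sum(dG^2)
    sBB <- if (denom > 0) sum(dX * dG) / denom else st
    s <- if (is.finite(sBB) && sBB > 0) min(max(sBB, 1e-8), 10) else st * 2
    dec <- e0 - e1
    X <- X1; e0 <- e1; G <- G1
    traj <- c(traj, e0)
    if (dec < config$tol) { converged <- TRUE; break }
  }
  coords(model) <- X
  attr(model, "trajectory") <- traj
  attr(model, "converged") <- converged
  model
}

#' The weight-snap maneuver
#'
#' Three sequential refinements with the density weight multiplied by a
#' very high, then a very low, then the default factor. Temporarily
#' prioritizing each term in turn can break the stalemate between density
#' and geometry and release high-strain density-misfit barrier traps;
#' low-strain traps are recalcitrant to it.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param target a \linkS4class{DensityGrid}.
#' @param config base \code{\link{refineConfig}}.
#' @param factors multipliers applied to \code{config$wx} in order.
#' @param restraints optional prebuilt restraints.
#' @param library restraint library.
#' @return the final model with attribute \code{wETrajectory} (wE after
#'   each stage).
#' @export
weightSnap <- function(model, target, config = refineConfig(),
                       factors = c(100, 0.01, 1), restraints = NULL,
                       library = NULL) {
  if (is.null(library)) library <- defaultLibrary(model)
  if (is.null(restraints)) restraints <- buildRestraints(model, library)
  wes <- numeric(0)
  cur <- model
  for (f in factors) {
    cfg <- config
    cfg$wx <- config$wx * f
    cur <- localRefine(cur, target, restraints, cfg, library)
    wes <- c(wes, wE(weScore(cur, restraints)))
  }
  attr(cur, "wETrajectory") <- wes
  cur
}
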