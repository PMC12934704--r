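#' @include modelIO.R
NULL

# Resolve the site id of atom key `k` at conformer letter `l`: a site with
# that letter, else a blank (unsplit) site, else NA.
resolveSite <- function(akey, alt, k, l) {
  s <- which(akey == k & alt == l)
  if (length(s)) return(s[1])
  s <- which(akey == k & alt == "")
  if (length(s)) s[1] else NA_integer_
}

#' Build a restraint set for a model
#'
#' Bonded terms (bonds from the library's residue templates plus peptide
#' and disulfide links; angles derived from all bonded triplets; torsions
#' from explicit records) are instantiated once per conformer letter using
#' cognate sites only: every atom in a term carries the same letter or is
#' blank. Nonbond pairs are all conformer-compatible site pairs within the
#' library cutoff whose atoms are separated by more than three bonds
#' (1-2, 1-3 and 1-4 pairs excluded); each pair's optimal separation r0 is
#' the sum of van der Waals radii.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param library a \code{restraintLibrary}; default chosen from the
#'   residues present.
#' @return a \linkS4class{RestraintSet}.
#' @export
buildRestraints <- function(model, library = NULL) {
  if (is.null(library)) library <- defaultLibrary(model)
  a <- model@atoms
  akey <- makeAtomKeys(a)
  unknown <- setdiff(unique(a$resname), library$residues)
  if (length(unknown))
    stopf("no residue template for: %s", paste(unknown, collapse = ", "))

  letters <- model@conformerLetters
  kb <- model@bonds

  resOf <- function(k) sub("\\|[^|]+$", "", k)
  nameOf <- function(k) sub("^.*\\|", "", k)

  # --- bonds ---
  bres <- list()
  for (i in seq_len(nrow(kb))) {
    k1 <- kb$key1[i]; k2 <- kb$key2[i]
    kind <- kb$kind[i]
    vs <- switch(kind,
      intra = libBondLookup(library, sub("^.*\\|([^|]+)\\|[^|]+$", "\\1", k1),
                            nameOf(k1), nameOf(k2)),
      link = libLinkBondLookup(library, nameOf(k1), nameOf(k2)),
      ss = library$ssBond)
    if (is.null(vs)) next
    for (l in letters) {
      s1 <- resolveSite(akey, a$alt, k1, l)
      s2 <- resolveSite(akey, a$alt, k2, l)
      if (is.na(s1) || is.na(s2)) next
      bres[[length(bres) + 1]] <- c(min(s1, s2), max(s1, s2), vs["v0"],
                                    vs["sigma"])
    }
  }
  bondsDf <- if (length(bres)) {
    m <- do.call(rbind, bres)
    df <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                     v0 = m[, 3], sigma = m[, 4])
    df <- df[!duplicated(df[, c("i", "j")]), , drop = FALSE]
    df[order(df$i, df$j), , drop = FALSE]
  } else data.frame(i = integer(0), j = integer(0), v0 = numeric(0),
                    sigma = numeric(0))

  # --- angles: all bonded triplets through non-disulfide bonds ---
  kbnd <- kb[kb$kind != "ss", , drop = FALSE]
  adj <- split(c(kbnd$key2, kbnd$key1), c(kbnd$key1, kbnd$key2))
  ares <- list()
  # residue order along the model, for link-angle offsets
  resTab <- unique(data.frame(rkey = makeResidueKeys(a), chain = a$chain,
                              resno = a$resno, ins = a$ins,
                              stringsAsFactors = FALSE))
  resTab <- resTab[order(resTab$chain, resTab$resno, resTab$ins), ,
                   drop = FALSE]
  resOrder <- setNames(seq_len(nrow(resTab)), resTab$rkey)
  for (ctr in names(adj)) {
    nb <- sort(unique(adj[[ctr]]))
    if (length(nb) < 2) next
    for (p in seq_len(length(nb) - 1)) for (q in seq(p + 1, length(nb))) {
      trip <- c(nb[p], ctr, nb[q])
      rs <- vapply(trip, resOf, "")
      if (length(unique(rs)) == 1) {
        vs <- libAngleLookup(library, sub("^.*\\|", "", rs[1]),
                             vapply(trip, nameOf, ""), c(0L, 0L, 0L))
      } else {
        offs <- unname(resOrder[rs])
        if (diff(range(offs)) > 1) next
        vs <- libAngleLookup(library, sub("^.*\\|", "", rs[2]),
                             vapply(trip, nameOf, ""),
                             as.integer(offs - min(offs)))
      }
      for (l in letters) {
        ss <- vapply(trip, function(k) resolveSite(akey, a$alt, k, l), 1L)
        if (anyNA(ss)) next
        ares[[length(ares) + 1]] <- c(ss, vs["v0"], vs["sigma"])
      }
    }
  }
  anglesDf <- if (length(ares)) {
    m <- do.call(rbind, ares)
    df <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                     k = as.integer(m[, 3]), v0 = m[, 4], sigma = m[, 5])
    # canonical orientation (smaller flank first), dedupe per letter
    flip <- df$i > df$k
    tmp <- df$i[flip]; df$i[flip] <- df$k[flip]; df$k[flip] <- tmp
    df <- df[!duplicated(df[, c("i", "j", "k")]), , drop = FALSE]
    df[order(df$j, df$i, df$k), , drop = FALSE]
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    v0 = numeric(0), sigma = numeric(0))

  # --- torsions: explicit intra-residue records only ---
  tres <- list()
  lt <- library$torsions
  if (nrow(lt)) {
    rkeys <- unique(makeResidueKeys(a))
    for (rk in rkeys) {
      rn <- sub("^.*\\|", "", rk)
      recs <- lt[lt$res == rn | lt$res == "*", , drop = FALSE]
      for (j in seq_len(nrow(recs))) {
        kq <- paste(rk, c(recs$a1[j], recs$a2[j], recs$a3[j], recs$a4[j]),
                    sep = "|")
        for (l in letters) {
          ss <- vapply(kq, function(k) resolveSite(akey, a$alt, k, l), 1L)
          if (anyNA(ss)) next
          tres[[length(tres) + 1]] <- c(ss, recs$v0[j], recs$sigma[j],
                                        recs$period[j])
        }
      }
    }
  }
  torsDf <- if (length(tres)) {
    m <- do.call(rbind, tres)
    df <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                     k = as.integer(m[, 3]), l = as.integer(m[, 4]),
                     v0 = m[, 5], sigma = m[, 6], period = as.integer(m[, 7]))
    df <- df[!duplicated(df[, 1:4]), , drop = FALSE]
    df[order(df$i, df$j, df$k, df$l), , drop = FALSE]
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    l = integer(0), v0 = numeric(0), sigma = numeric(0),
                    period = integer(0))

  # --- nonbond pairs ---
  nbDf <- buildNonbond(model, library, akey)

  new("RestraintSet", bonds = bondsDf, angles = anglesDf, torsions = torsDf,
      nonbond = nbDf, clashMargin = library$clashMargin)
}

# Conformer-compatible pairs within the cutoff, excluding pairs separated
# by <= 3 bonds in the atom-key graph (disulfides count as bonds here).
buildNonbond <- function(model, library, akey = atomKeys(model)) {
  a <- model@atoms
  n <- nrow(a)
  empty <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
  if (n < 2) return(empty)

  # key-graph neighborhoods up to depth 3
  b <- model@bonds
  adj <- split(c(b$key2, b$key1), c(b$key1, b$key2))
  ukeys <- unique(akey)
  near <- lapply(ukeys, function(k) {
    seen <- k
    frontier <- k
    for (d in 1:3) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  })
  names(near) <- ukeys

  X <- coords(model)
  cutoff <- library$cutoff
  rad <- libVdw(library, a$element)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    js <- seq(i + 1, n)
    d2 <- (X[js, 1] - X[i, 1])^2 + (X[js, 2] - X[i, 2])^2 +
      (X[js, 3] - X[i, 3])^2
    js <- js[d2 <= cutoff^2]
    if (!length(js)) next
    # conformer compatibility: same letter, or at least one blank
    ai <- a$alt[i]
    compat <- a$alt[js] == ai | a$alt[js] == "" | ai == ""
    js <- js[compat]
    if (!length(js)) next
    excl <- akey[js] %in% near[[akey[i]]]
    js <- js[!excl]
    if (!length(js)) next
    pairs[[length(pairs) + 1]] <-
      data.frame(i = i, j = js, r0 = rad[i] + rad[js])
  }
  if (!length(pairs)) return(empty)
  out <- do.call(rbind, pairs)
  out[order(out$i, out$j), , drop = FALSE]
}

# ---- evaluation ------------------------------------------------------------

#' Signed deviates of all bonded terms
#'
#' Each term's deviate is d = (v - v0)/sigma, with torsion differences
#' wrapped to (-180, 180] before division; the statistical energy of a term
#' is E = d^2. Degenerate (colinear) angles or torsions yield NA deviates
#' and are reported with a warning.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param restraints a \linkS4class{RestraintSet}.
#' @return list with numeric vectors \code{bond}, \code{angle},
#'   \code{torsion} (signed deviates, NA when undefined).
#' @export
termDeviates <- function(model, restraints) {
  X <- coords(model)
  r <- restraints
  out <- list(bond = numeric(0), angle = numeric(0), torsion = numeric(0))
  if (nrow(r@bonds))
    out$bond <- cpp_bond_terms(X, as.matrix(r@bonds[, c("i", "j")]),
                               r@bonds$v0, r@bonds$sigma, FALSE)$dev
  if (nrow(r@angles))
    out$angle <- cpp_angle_terms(X, as.matrix(r@angles[, c("i", "j", "k")]),
                                 r@angles$v0, r@angles$sigma, FALSE)$dev
  if (nrow(r@torsions))
    out$torsion <- cpp_torsion_terms(
      X, as.matrix(r@torsions[, c("i", "j", "k", "l")]),
      r@torsions$v0, r@torsions$sigma, r@torsions$period, FALSE)$dev
  nbad <- sum(is.na(out$angle)) + sum(is.na(out$torsion))
  if (nbad)
    warnf("%d degenerate angle/torsion term(s) excluded", nbad)
  out
}

#' Normalized Lennard-Jones energies of the nonbond pairs
#'
#' E(r) = (r0/r)^12 - 2 (r0/r)^6, with minimum exactly -1 at r = r0 and 0
#' at infinite separation.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param restraints a \linkS4class{RestraintSet}.
#' @return numeric vector of pair energies (with attribute \code{r}, the
#'   pair distances).
#' @export
ljEnergies <- function(model, restraints) {
  nb <- restraints@nonbond
  if (!nrow(nb)) return(numeric(0))
  res <- cpp_lj_terms(coords(model), as.matrix(nb[, c("i", "j")]), nb$r0,
                      FALSE)
  structure(res$e, r = res$r)
}

#' Normalized Lennard-Jones energy at given separations
#'
#' @param r distance(s), Angstrom.
#' @param r0 optimal separation(s), Angstrom.
#' @return numeric vector of energies in [-1, Inf).
#' @export
ljEnergy <- function(r, r0) {
  if (any(r <= 0)) stopf("coincident non-bonded atoms (r = 0)")
  s6 <- (r0 / r)^6
  s6 * s6 - 2 * s6
}

# Clash deviates from the nonbond pairs: overlap beyond the margin, in
# units of 0.1 A.
clashDeviates <- function(model, restraints) {
  nb <- restraints@nonbond
  if (!nrow(nb)) return(numeric(0))
  e <- ljEnergies(model, restraints)
  r <- attr(e, "r")
  overlap <- nb$r0 - r
  dev <- pmax(0, overlap - restraints@clashMargin) / 0.1
  dev[dev > 0]
}

#' Absolute deviates per validation category
#'
#' Returns the complete, deterministically ordered multiset of |d| for each
#' statistical category of the model. Categories with no terms are present
#' and empty; the \code{nonbond} category is reported as energies by
#' \code{\link{ljEnergies}}, not here.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param restraints a \linkS4class{RestraintSet}; built on the fly when
#'   omitted.
#' @param library restraint library used when \code{restraints} is missing.
#' @return named list of numeric vectors, one per category.
#' @export
categoryDeviates <- function(model, restraints = NULL, library = NULL) {
  if (is.null(restraints)) restraints <- buildRestraints(model, library)
  dv <- suppressWarnings(termDeviates(model, restraints))
  list(
    bond = abs(dv$bond[!is.na(dv$bond)]),
    angle = abs(dv$angle[!is.na(dv$angle)]),
    torsion = abs(dv$torsion[!is.na(dv$torsion)]),
    planarity = numeric(0),
    chirality = numeric(0),
    omega = numeric(0),
    cbeta = numeric(0),
    rotamer = numeric(0),
    ramachandran = numeric(0),
    clash = clashDeviates(model, restraints)
  )
}

#' Per-site statistical energy
#'
#' The sum of E = d^2 over every bonded term containing the site (each
#' term's full energy, not apportioned among its atoms) plus the site's
#' Lennard-Jones pair energies. Used as the rectification criterion of the
#' rectified simulated annealing maneuver.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param restraints a \linkS4class{RestraintSet}; built when omitted.
#' @param library library used when \code{restraints} is missing.
#' @return numeric vector, one energy per site.
#' @export
perAtomEnergy <- function(model, restraints = NULL, library = NULL) {
  if (is.null(restraints)) restraints <- buildRestraints(model, library)
  n <- nrow(model@atoms)
  out <- numeric(n)
  dv <- suppressWarnings(termDeviates(model, restraints))
  addTerm <- function(df, cols, dev) {
    e <- dev^2
    e[is.na(e)] <- 0
    for (cl in cols) {
      idx <- df[[cl]]
      for (t in seq_along(idx)) out[idx[t]] <<- out[idx[t]] + e[t]
    }
  }
  if (nrow(restraints@bonds)) addTerm(restraints@bonds, c("i", "j"), dv$bond)
  if (nrow(restraints@angles))
    addTerm(restraints@angles, c("i", "j", "k"), dv$angle)
  if (nrow(restraints@torsions))
    addTerm(restraints@torsions, c("i", "j", "k", "l"), dv$torsion)
  nb <- restraints@nonbond
  if (nrow(nb)) {
    e <- as.numeric(ljEnergies(model, restraints))
    for (t in seq_len(nrow(nb))) {
      out[nb$i[t]] <- out[nb$i[t]] + e[t]
      out[nb$j[t]] <- out[nb$j[t]] + e[t]
    }
  }
  out
}
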