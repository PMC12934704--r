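#' @include restraintLibrary.R AllGenerics.R
NULL

# ---- construction ----------------------------------------------------------

#' Create an EnsembleModel from an atom table
#'
#' Covalent bonds are inferred from the restraint library's residue
#' templates plus inter-residue peptide links (sequential C-N closer than
#' 1.8 A) and disulfides (SG-SG closer than 2.5 A). Missing occupancies
#' default to 1/number-of-conformer-letters for split atoms and 1
#' otherwise.
#'
#' @param atoms data.frame with columns \code{name}, \code{resname},
#'   \code{chain}, \code{resno}, \code{ins}, \code{alt}, \code{occ},
#'   \code{b}, \code{x}, \code{y}, \code{z} and optionally \code{element}.
#' @param library a \code{restraintLibrary} used for bond templates; by
#'   default chosen from the residue names present.
#' @param conformerLetters ordered set of conformer letters; defaults to
#'   the letters present, or \code{c("A", "B")} if none.
#' @return an \linkS4class{EnsembleModel}.
#' @export
ensembleModel <- function(atoms, library = NULL, conformerLetters = NULL) {
  a <- as.data.frame(atoms, stringsAsFactors = FALSE)
  a$ins <- a$ins %||% ""
  a$ins[is.na(a$ins)] <- ""
  a$alt[is.na(a$alt)] <- ""
  if (is.null(a$element)) a$element <- guessElement(a$name)
  a$element[is.na(a$element) | a$element == ""] <-
    guessElement(a$name[is.na(a$element) | a$element == ""])
  letters <- conformerLetters %||% {
    pres <- sort(unique(a$alt[a$alt != ""]))
    if (length(pres)) pres else c("A", "B")
  }
  if (is.null(a$occ)) a$occ <- NA_real_
  a$occ[is.na(a$occ) & a$alt == ""] <- 1
  a$occ[is.na(a$occ)] <- 1 / length(letters)
  if (is.null(a$b)) a$b <- 10
  a$b[is.na(a$b) | a$b <= 0] <- 10
  a <- a[, c("name", "resname", "chain", "resno", "ins", "alt", "occ", "b",
             "x", "y", "z", "element")]
  rownames(a) <- NULL

  mdl <- new("EnsembleModel", atoms = a,
             bonds = data.frame(key1 = character(0), key2 = character(0),
                                kind = character(0)),
             conformerLetters = letters)
  if (is.null(library)) library <- defaultLibrary(mdl)
  mdl@bonds <- inferBonds(mdl, library)
  validObject(mdl)
  checkOccupancySums(mdl)
  mdl
}

checkOccupancySums <- function(model) {
  a <- model@atoms
  split <- a$alt != ""
  if (!any(split)) return(invisible(NULL))
  keys <- makeAtomKeys(a[split, , drop = FALSE])
  sums <- tapply(a$occ[split], keys, sum)
  bad <- names(sums)[sums > 1 + 1e-6]
  if (length(bad))
    warnf("occupancies sum to > 1 for %d split group(s), e.g. %s",
          length(bad), bad[1])
  invisible(NULL)
}

# Infer the covalent bond graph (atom-key level) from library templates.
inferBonds <- function(model, library) {
  a <- model@atoms
  if (!nrow(a))
    return(data.frame(key1 = character(0), key2 = character(0),
                      kind = character(0)))
  akey <- makeAtomKeys(a)
  rkey <- makeResidueKeys(a)
  unknown <- setdiff(unique(a$resname), library$residues)
  if (length(unknown))
    stopf("no residue template for: %s", paste(unknown, collapse = ", "))

  res <- unique(data.frame(rkey = rkey, chain = a$chain, resno = a$resno,
                           ins = a$ins, resname = a$resname,
                           stringsAsFactors = FALSE))
  out <- list()
  add <- function(k1, k2, kind) {
    out[[length(out) + 1]] <<- data.frame(key1 = k1, key2 = k2, kind = kind,
                                          stringsAsFactors = FALSE)
  }

  lb <- library$bonds
  for (i in seq_len(nrow(res))) {
    rn <- res$resname[i]
    names_here <- unique(a$name[rkey == res$rkey[i]])
    recs <- lb[lb$res == rn | lb$res == "*", , drop = FALSE]
    if (nrow(recs)) {
      keep <- recs$a1 %in% names_here & recs$a2 %in% names_here
      recs <- recs[keep, , drop = FALSE]
      if (nrow(recs)) {
        # drop wildcard duplicates of residue-specific pairs
        pair <- paste(pmin(recs$a1, recs$a2), pmax(recs$a1, recs$a2))
        recs <- recs[!duplicated(pair), , drop = FALSE]
        for (j in seq_len(nrow(recs)))
          add(paste(res$rkey[i], recs$a1[j], sep = "|"),
              paste(res$rkey[i], recs$a2[j], sep = "|"), "intra")
      }
    }
    # generic hydrogens: attach to nearest heavy atom of the same residue
    hn <- names_here[guessElement(names_here) == "H"]
    hn <- setdiff(hn, recs$a1[guessElement(recs$a1) == "H"])
    hn <- setdiff(hn, recs$a2[guessElement(recs$a2) == "H"])
    covered <- unique(c(recs$a1, recs$a2))
    for (h in setdiff(hn, covered)) {
      hs <- which(rkey == res$rkey[i] & a$name == h)[1]
      heavy <- which(rkey == res$rkey[i] & guessElement(a$name) != "H")
      if (!length(heavy)) next
      d2 <- (a$x[heavy] - a$x[hs])^2 + (a$y[heavy] - a$y[hs])^2 +
        (a$z[heavy] - a$z[hs])^2
      nb <- heavy[which.min(d2)]
      add(paste(res$rkey[i], h, sep = "|"),
          paste(res$rkey[i], a$name[nb], sep = "|"), "intra")
    }
  }

  # peptide links between sequential residues of the same chain
  keyDist <- function(k1, k2) {
    s1 <- which(akey == k1); s2 <- which(akey == k2)
    if (!length(s1) || !length(s2)) return(Inf)
    min(sqrt(outer(a$x[s1], a$x[s2], "-")^2 +
             outer(a$y[s1], a$y[s2], "-")^2 +
             outer(a$z[s1], a$z[s2], "-")^2))
  }
  for (ch in unique(res$chain)) {
    rs <- res[res$chain == ch, , drop = FALSE]
    rs <- rs[order(rs$resno, rs$ins), , drop = FALSE]
    if (nrow(rs) < 2) next
    for (i in seq_len(nrow(rs) - 1)) {
      k1 <- paste(rs$rkey[i], "C", sep = "|")
      k2 <- paste(rs$rkey[i + 1], "N", sep = "|")
      if (k1 %in% akey && k2 %in% akey && keyDist(k1, k2) < 1.8)
        add(k1, k2, "link")
    }
  }

  # disulfides: SG-SG below 2.5 A between different residues
  sg <- which(a$name == "SG")
  if (length(sg) > 1) {
    done <- character(0)
    for (i in sg) for (j in sg) {
      if (i >= j || rkey[i] == rkey[j]) next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
      id <- paste(akey[i], akey[j])
      if (d < 2.5 && !(id %in% done)) {
        add(akey[i], akey[j], "ss")
        done <- c(done, id)
      }
    }
  }

  if (!length(out))
    return(data.frame(key1 = character(0), key2 = character(0),
                      kind = character(0)))
  b <- do.call(rbind, out)
  b <- b[!duplicated(paste(pmin(b$key1, b$key2), pmax(b$key1, b$key2))), ,
         drop = FALSE]
  rownames(b) <- NULL
  b
}

# ---- PDB reading / writing -------------------------------------------------

#' Read a multi-conformer structure from a PDB file
#'
#' Atom records are parsed with \pkg{bio3d} (keeping all altlocs); every
#' atom name carrying two or more altloc letters within a residue becomes a
#' split group, and covalent bonds are inferred from residue templates plus
#' peptide and disulfide links.
#'
#' @param path path to a PDB file.
#' @param library restraint library for bond templates (default: chosen
#'   from the residues present).
#' @return an \linkS4class{EnsembleModel}.
#' @export
readEnsemblePDB <- function(path, library = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atomLines <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in atomLines) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stopf("unparsable ATOM record at line %d: too short", i)
    nums <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(nums)))))
      stopf("unparsable coordinates at line %d", i)
  }
  p <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- p$atom
  atoms <- data.frame(
    name = at$elety, resname = at$resid, chain = at$chain,
    resno = at$resno,
    ins = ifelse(is.na(at$insert), "", at$insert),
    alt = ifelse(is.na(at$alt), "", at$alt),
    occ = at$o, b = at$b, x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     guessElement(at$elety), at$elesy),
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  ensembleModel(atoms, library = library)
}

#' Write an EnsembleModel to a PDB file
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEnsemblePDB <- function(model, path) {
  a <- model@atoms
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$name, chain = a$chain,
    insert = ifelse(a$ins == "", NA, a$ins),
    alt = ifelse(a$alt == "", NA, a$alt),
    o = a$occ, b = a$b, elesy = a$element)
  invisible(path)
}

# ---- split groups and swaps ------------------------------------------------

#' Split groups of a model
#'
#' A split group is an atom (one atom key) represented by two or more sites
#' with distinct altloc letters.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @return data.frame with columns \code{key}, \code{n} and \code{letters}
#'   (comma-separated), ordered by key.
#' @export
splitGroups <- function(model) {
  a <- model@atoms
  lettered <- a$alt != ""
  if (!any(lettered))
    return(data.frame(key = character(0), n = integer(0),
                      letters = character(0)))
  keys <- makeAtomKeys(a[lettered, , drop = FALSE])
  tab <- tapply(a$alt[lettered], keys, function(x) sort(unique(x)))
  n <- vapply(tab, length, 1L)
  out <- data.frame(key = names(tab), n = as.integer(n),
                    letters = vapply(tab, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[out$n >= 2, , drop = FALSE]
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sites of one split group
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param key an atom key.
#' @return named integer vector of site ids, names are altloc letters.
#' @export
groupSites <- function(model, key) {
  akey <- atomKeys(model)
  s <- which(akey == key & model@atoms$alt != "")
  if (!length(s)) stopf("no split group with key '%s'", key)
  setNames(s, model@atoms$alt[s])
}

#' Construct a set of conformer-letter swap moves
#'
#' @param keys character vector of atom keys to swap together as one move,
#'   or a list of such vectors (one entry per move).
#' @param perm named character vector mapping old letters to new letters;
#'   default exchanges A and B.
#' @return an object of class \code{swapSet}.
#' @export
swapSet <- function(keys, perm = c(A = "B", B = "A")) {
  if (!is.list(keys)) keys <- list(keys)
  if (is.null(names(perm)) || anyDuplicated(unname(perm)) ||
      !setequal(names(perm), unname(perm)))
    stopf("perm must be a bijection on the conformer letters")
  moves <- lapply(keys, function(k) list(keys = as.character(k),
                                         perm = perm))
  structure(list(moves = moves), class = "swapSet")
}

#' @export
print.swapSet <- function(x, ...) {
  cat("swapSet:", length(x$moves), "move(s)\n")
  invisible(x)
}

#' Apply conformer-letter swaps to a model
#'
#' Only altloc letters change; coordinates, occupancies and B factors are
#' untouched. For two-letter models applying the same \code{swapSet} twice
#' restores the original assignment.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param swaps a \code{swapSet}.
#' @return the model with letters permuted.
#' @export
applySwaps <- function(model, swaps) {
  stopifnot(is(model, "EnsembleModel"), inherits(swaps, "swapSet"))
  a <- model@atoms
  akey <- makeAtomKeys(a)
  sg <- splitGroups(model)
  for (mv in swaps$moves) {
    perm <- mv$perm
    if (!setequal(names(perm), model@conformerLetters))
      stopf("swap permutation must cover letters %s",
            paste(model@conformerLetters, collapse = ","))
    for (k in mv$keys) {
      if (!(k %in% sg$key))
        stopf("cannot swap '%s': not a split group", k)
      sel <- akey == k & a$alt != ""
      a$alt[sel] <- unname(perm[a$alt[sel]])
    }
  }
  model@atoms <- a
  model
}

# ---- downstream traversal --------------------------------------------------

# Rank atoms for the downstream direction: increasing residue order along
# each chain; within a residue main chain (N, CA, C, then O/OXT) before side
# chain, side chain ordered by bond-graph distance from CA.
atomRanks <- function(model) {
  a <- model@atoms
  akey <- makeAtomKeys(a)
  rkey <- makeResidueKeys(a)
  ukeys <- unique(akey)
  urkey <- rkey[match(ukeys, akey)]
  uname <- a$name[match(ukeys, akey)]

  res <- unique(data.frame(rkey = rkey, chain = a$chain, resno = a$resno,
                           ins = a$ins, stringsAsFactors = FALSE))
  res <- res[order(res$chain, res$resno, res$ins), , drop = FALSE]
  resOrd <- setNames(seq_len(nrow(res)), res$rkey)

  mainOrder <- c(N = 0, CA = 1, C = 2, O = 3, OXT = 3.5)
  tier <- rep(NA_real_, length(ukeys))
  mc <- uname %in% names(mainOrder)
  tier[mc] <- mainOrder[uname[mc]]

  # side-chain tier: 5 + bond distance from CA within the residue subgraph
  b <- model@bonds
  adj <- split(c(b$key2, b$key1), c(b$key1, b$key2))
  for (rk in unique(urkey)) {
    sel <- which(urkey == rk & !mc)
    if (!length(sel)) next
    caKey <- ukeys[urkey == rk & uname == "CA"]
    dist <- setNames(rep(Inf, length(sel)), ukeys[sel])
    if (length(caKey)) {
      frontier <- caKey
      d <- 0
      seen <- caKey
      while (length(frontier)) {
        d <- d + 1
        nxt <- unique(unlist(adj[frontier], use.names = FALSE))
        nxt <- setdiff(nxt[nxt %in% ukeys[urkey == rk]], seen)
        if (!length(nxt)) break
        hit <- intersect(nxt, names(dist))
        dist[hit] <- pmin(dist[hit], d)
        seen <- c(seen, nxt)
        frontier <- nxt
      }
    }
    dist[!is.finite(dist)] <- 50
    tier[sel] <- 5 + dist[ukeys[sel]]
  }
  ord <- order(resOrd[urkey], tier, uname)
  setNames(seq_along(ukeys), ukeys[ord])
}

#' Atoms downstream of a given atom
#'
#' Returns the atom plus all atoms reachable in the downstream direction
#' (toward the C terminus; main chain before side chain, side chains away
#' from CA). Traversal is not propagated across disulfide bonds, and ring
#' closures are visited at most once, so it terminates on all inputs.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param key an atom key present in the model.
#' @return character vector of atom keys (always contains \code{key}).
#' @export
downstreamAtoms <- function(model, key) {
  akey <- unique(atomKeys(model))
  if (!(key %in% akey)) stopf("unknown atom key '%s'", key)
  rank <- atomRanks(model)
  b <- model@bonds[model@bonds$kind != "ss", , drop = FALSE]
  # direct each bond from lower to higher rank
  lo <- ifelse(rank[b$key1] <= rank[b$key2], b$key1, b$key2)
  hi <- ifelse(rank[b$key1] <= rank[b$key2], b$key2, b$key1)
  adj <- split(hi, lo)
  seen <- key
  frontier <- key
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

# ---- assignment comparison -------------------------------------------------

#' Compare conformer assignments between a model and a reference
#'
#' For each shared split group, decides whether the model's letter-to-
#' position mapping matches the reference (pairing members by proximity),
#' then chooses the global letter relabeling that maximizes matches, since
#' conformer naming is arbitrary.
#'
#' @param model,reference \linkS4class{EnsembleModel}s sharing the same
#'   split-group keys.
#' @return list with \code{perGroup} (data.frame \code{key},
#'   \code{sameAsReference} under the best global relabeling) and
#'   \code{percentMatch}.
#' @export
assignmentMatch <- function(model, reference) {
  gm <- splitGroups(model)
  gr <- splitGroups(reference)
  if (!setequal(gm$key, gr$key)) {
    onlyM <- setdiff(gm$key, gr$key)
    onlyR <- setdiff(gr$key, gm$key)
    stopf("split groups differ; only in model: %s; only in reference: %s",
          paste(head(onlyM, 3), collapse = ","),
          paste(head(onlyR, 3), collapse = ","))
  }
  keys <- sort(gm$key)
  state <- logical(length(keys))   # TRUE = identity pairing closer
  for (i in seq_along(keys)) {
    sm <- groupSites(model, keys[i])
    sr <- groupSites(reference, keys[i])
    letters <- sort(names(sm))
    pm <- coords(model)[sm[letters], , drop = FALSE]
    pr <- coords(reference)[sr[letters], , drop = FALSE]
    idCost <- sum((pm - pr)^2)
    swCost <- sum((pm - pr[rev(seq_len(nrow(pr))), , drop = FALSE])^2)
    state[i] <- idCost <= swCost
  }
  nId <- sum(state)
  flip <- (length(state) - nId) > nId
  same <- if (flip) !state else state
  list(
    perGroup = data.frame(key = keys, sameAsReference = same,
                          stringsAsFactors = FALSE),
    percentMatch = 100 * sum(same) / length(same)
  )
}
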