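#' @include utils.R
NULL

#' Read a restraint library from structured text
#'
#' A library is a plain-text file with one record per line:
#' \preformatted{
#'   residue RES
#'   bond RES A1 A2 v0 sigma           # RES may be "*" (any residue)
#'   angle RES A1 A2 A3 v0 sigma
#'   torsion RES A1 A2 A3 A4 v0 sigma period
#'   link bond C +N v0 sigma           # "+" marks the next residue
#'   link angle CA C +N v0 sigma
#'   link ss SG SG v0 sigma            # disulfide bridge
#'   default angle v0 sigma
#'   vdw ELEM radius
#'   nonbond cutoff r
#'   clash margin m
#' }
#' Bond topology is taken from the bond records, so the same file defines
#' both connectivity and ideal geometry. Two libraries ship with the
#' package: a bead-peptide toy chemistry (\code{beadLibrary()}) and a coarse
#' amino-acid library (\code{aminoLibrary()}).
#'
#' @param path path to a library file.
#' @return an object of class \code{restraintLibrary}.
#' @export
readRestraintLibrary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")

  bonds <- list(); angles <- list(); torsions <- list()
  linkBonds <- list(); linkAngles <- list()
  residues <- character(0)
  vdw <- numeric(0)
  ssBond <- NULL
  defAngle <- c(v0 = 109.5, sigma = 3.0)
  cutoff <- 5.0
  clashMargin <- 0.4

  for (i in seq_along(toks)) {
    t <- toks[[i]]
    rec <- t[1]
    if (rec == "residue") {
      residues <- c(residues, t[2])
    } else if (rec == "bond") {
      bonds[[length(bonds) + 1]] <- data.frame(
        res = t[2], a1 = t[3], a2 = t[4],
        v0 = as.numeric(t[5]), sigma = as.numeric(t[6]))
    } else if (rec == "angle") {
      angles[[length(angles) + 1]] <- data.frame(
        res = t[2], a1 = t[3], a2 = t[4], a3 = t[5],
        v0 = as.numeric(t[6]), sigma = as.numeric(t[7]))
    } else if (rec == "torsion") {
      torsions[[length(torsions) + 1]] <- data.frame(
        res = t[2], a1 = t[3], a2 = t[4], a3 = t[5], a4 = t[6],
        v0 = as.numeric(t[7]), sigma = as.numeric(t[8]),
        period = as.integer(t[9]))
    } else if (rec == "link" && t[2] == "bond") {
      linkBonds[[length(linkBonds) + 1]] <- data.frame(
        a1 = t[3], a2 = t[4],
        v0 = as.numeric(t[5]), sigma = as.numeric(t[6]))
    } else if (rec == "link" && t[2] == "angle") {
      linkAngles[[length(linkAngles) + 1]] <- data.frame(
        a1 = t[3], a2 = t[4], a3 = t[5],
        v0 = as.numeric(t[6]), sigma = as.numeric(t[7]))
    } else if (rec == "link" && t[2] == "ss") {
      ssBond <- c(v0 = as.numeric(t[5]), sigma = as.numeric(t[6]))
    } else if (rec == "default" && t[2] == "angle") {
      defAngle <- c(v0 = as.numeric(t[3]), sigma = as.numeric(t[4]))
    } else if (rec == "vdw") {
      vdw[t[2]] <- as.numeric(t[3])
    } else if (rec == "nonbond" && t[2] == "cutoff") {
      cutoff <- as.numeric(t[3])
    } else if (rec == "clash" && t[2] == "margin") {
      clashMargin <- as.numeric(t[3])
    } else {
      stopf("unparsable library record at line matching '%s'",
            paste(t, collapse = " "))
    }
  }

  bindRows <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame()
  lib <- list(
    bonds = bindRows(bonds),
    angles = bindRows(angles),
    torsions = bindRows(torsions),
    linkBonds = bindRows(linkBonds),
    linkAngles = bindRows(linkAngles),
    ssBond = ssBond %||% c(v0 = 2.033, sigma = 0.016),
    defAngle = defAngle,
    vdw = vdw,
    cutoff = cutoff,
    clashMargin = clashMargin,
    residues = unique(c(residues,
                        if (nrow(bindRows(bonds))) bindRows(bonds)$res))
  )
  lib$residues <- setdiff(lib$residues, "*")
  class(lib) <- "restraintLibrary"
  lib
}

libCache <- new.env(parent = emptyenv())

#' Built-in restraint libraries
#'
#' \code{beadLibrary()} is the bead-peptide toy chemistry used by the
#' synthetic fixture generator; \code{aminoLibrary()} is a coarse
#' amino-acid library used for topology inference on real residues.
#'
#' @return a \code{restraintLibrary}.
#' @export
beadLibrary <- function() {
  if (is.null(libCache$bead))
    libCache$bead <- readRestraintLibrary(
      system.file("extdata", "bead.lib", package = "untangler",
                  mustWork = TRUE))
  libCache$bead
}

#' @rdname beadLibrary
#' @export
aminoLibrary <- function() {
  if (is.null(libCache$aa))
    libCache$aa <- readRestraintLibrary(
      system.file("extdata", "aa_generic.lib", package = "untangler",
                  mustWork = TRUE))
  libCache$aa
}

#' @export
print.restraintLibrary <- function(x, ...) {
  cat("restraintLibrary:", length(x$residues), "residues,",
      nrow(x$bonds), "bond records,", nrow(x$angles), "angle records\n")
  invisible(x)
}

# Pick the library whose residues cover the model; bead chemistry wins when
# bead residues are present.
defaultLibrary <- function(model) {
  res <- unique(model@atoms$resname)
  if (any(res == "BEA")) beadLibrary() else aminoLibrary()
}

libVdw <- function(lib, element) {
  r <- lib$vdw[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

# Look up ideal value/sigma for an intra-residue bond a1-a2 of residue res.
libBondLookup <- function(lib, res, a1, a2) {
  b <- lib$bonds
  if (nrow(b)) {
    hit <- b[(b$res == res | b$res == "*") &
             ((b$a1 == a1 & b$a2 == a2) | (b$a1 == a2 & b$a2 == a1)), ,
             drop = FALSE]
    # residue-specific records win over wildcard ones
    if (nrow(hit)) {
      hit <- hit[order(hit$res == "*"), , drop = FALSE]
      return(c(v0 = hit$v0[1], sigma = hit$sigma[1]))
    }
  }
  NULL
}

libLinkBondLookup <- function(lib, a1, a2) {
  b <- lib$linkBonds
  if (nrow(b)) {
    n1 <- sub("^\\+", "", b$a1); n2 <- sub("^\\+", "", b$a2)
    hit <- which((n1 == a1 & n2 == a2) | (n1 == a2 & n2 == a1))
    if (length(hit))
      return(c(v0 = b$v0[hit[1]], sigma = b$sigma[hit[1]]))
  }
  NULL
}

# Angle lookup for atoms (a, b, c) centred on b with residue offsets
# (off relative to the first residue in the triplet, 0 or 1).
libAngleLookup <- function(lib, res, names, offs) {
  names <- unname(names)
  offs <- as.integer(offs - min(offs))
  if (all(offs == 0)) {
    a <- lib$angles
    if (nrow(a)) {
      hit <- a[(a$res == res | a$res == "*") &
               ((a$a1 == names[1] & a$a2 == names[2] & a$a3 == names[3]) |
                (a$a1 == names[3] & a$a2 == names[2] & a$a3 == names[1])), ,
               drop = FALSE]
      if (nrow(hit)) {
        hit <- hit[order(hit$res == "*"), , drop = FALSE]
        return(c(v0 = hit$v0[1], sigma = hit$sigma[1]))
      }
    }
  } else {
    la <- lib$linkAngles
    if (nrow(la)) {
      for (i in seq_len(nrow(la))) {
        rn <- c(la$a1[i], la$a2[i], la$a3[i])
        ro <- as.integer(grepl("^\\+", rn))
        rn <- sub("^\\+", "", rn)
        rrev <- rev(ro); rrev <- rrev - min(rrev)
        if ((identical(rn, names) && identical(ro, offs)) ||
            (identical(rev(rn), names) && identical(rrev, offs)))
          return(c(v0 = la$v0[i], sigma = la$sigma[i]))
      }
    }
  }
  c(v0 = unname(lib$defAngle["v0"]), sigma = unname(lib$defAngle["sigma"]))
}
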