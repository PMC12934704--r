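#' @include untangler-package.R
NULL

#' EnsembleModel: a multi-conformer atomic model
#'
#' Holds atom sites (one row per site, so a split atom contributes one row
#' per altloc letter), the covalent bond graph over atom keys, and the
#' ordered set of conformer letters in use.
#'
#' An atom key is \code{chain|resno|ins|resname|name}; a residue key drops
#' the atom name. Sites sharing an atom key but carrying different altloc
#' letters form a split group.
#'
#' @slot atoms data.frame with columns \code{name}, \code{resname},
#'   \code{chain}, \code{resno}, \code{ins}, \code{alt}, \code{occ},
#'   \code{b}, \code{x}, \code{y}, \code{z}, \code{element}. Row order is
#'   the site id.
#' @slot bonds data.frame with columns \code{key1}, \code{key2},
#'   \code{kind} (\code{"intra"}, \code{"link"} or \code{"ss"} for
#'   disulfides); each covalent bond appears once, the graph is treated as
#'   symmetric.
#' @slot conformerLetters character vector of conformer letters (default
#'   \code{c("A", "B")}).
#' @export
setClass("EnsembleModel",
  representation(
    atoms = "data.frame",
    bonds = "data.frame",
    conformerLetters = "character"
  )
)

setValidity("EnsembleModel", function(object) {
  a <- object@atoms
  need <- c("name", "resname", "chain", "resno", "ins", "alt", "occ", "b",
            "x", "y", "z", "element")
  if (!all(need %in% names(a)))
    return(paste("atoms is missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a)) {
    if (any(a$occ < -1e-9 | a$occ > 1 + 1e-9))
      return("occupancies must lie in [0, 1]")
    if (any(a$b <= 0))
      return("B factors must be positive")
    lettered <- a$alt[a$alt != ""]
    if (length(lettered) && !all(lettered %in% object@conformerLetters))
      return("altloc letters present that are not in conformerLetters")
  }
  if (nrow(object@bonds) &&
      !all(c("key1", "key2", "kind") %in% names(object@bonds)))
    return("bonds must have columns key1, key2, kind")
  TRUE
})

#' RestraintSet: instantiated geometry restraints for one model
#'
#' Bonded terms are instantiated per conformer letter (cognate site pairs
#' only); the nonbond list holds all conformer-compatible pairs within the
#' build cutoff together with their optimal separations.
#'
#' @slot bonds data.frame \code{i, j, v0, sigma} (site ids; Angstrom).
#' @slot angles data.frame \code{i, j, k, v0, sigma} (degrees).
#' @slot torsions data.frame \code{i, j, k, l, v0, sigma, period} (degrees).
#' @slot nonbond data.frame \code{i, j, r0} with per-pair optimal
#'   separation r0 (sum of van der Waals radii, Angstrom).
#' @slot clashMargin numeric; nonbond overlap beyond this margin (Angstrom)
#'   counts toward the clash category.
#' @export
setClass("RestraintSet",
  representation(
    bonds = "data.frame",
    angles = "data.frame",
    torsions = "data.frame",
    nonbond = "data.frame",
    clashMargin = "numeric"
  )
)

setValidity("RestraintSet", function(object) {
  if (nrow(object@bonds) && any(object@bonds$sigma <= 0))
    return("bond sigmas must be positive")
  if (nrow(object@angles) && any(object@angles$sigma <= 0))
    return("angle sigmas must be positive")
  if (nrow(object@torsions) && any(object@torsions$sigma <= 0))
    return("torsion sigmas must be positive")
  if (nrow(object@nonbond) && any(object@nonbond$r0 <= 0))
    return("nonbond r0 must be positive")
  TRUE
})

#' DensityGrid: a 3-D scalar field on a regular isotropic grid
#'
#' @slot origin numeric(3), Angstrom position of voxel (0, 0, 0).
#' @slot spacing numeric(1), Angstrom per voxel (isotropic).
#' @slot values 3-D numeric array.
#' @export
setClass("DensityGrid",
  representation(
    origin = "numeric",
    spacing = "numeric",
    values = "array"
  )
)

setValidity("DensityGrid", function(object) {
  if (length(object@origin) != 3) return("origin must be length 3")
  if (length(object@spacing) != 1 || object@spacing <= 0)
    return("spacing must be a single positive number")
  d <- dim(object@values)
  if (length(d) != 3) return("values must be a 3-D array")
  if (any(d < 8)) return("grid must be at least 8 voxels along each axis")
  TRUE
})

#' WEScore: the weighted-energy model-quality score
#'
#' Per-category reports plus the scalar wE, defined as the sum over
#' categories of \code{wAvg * meanE + wWorst * clip(worstE)} plus the mean
#' normalized Lennard-Jones nonbond energy.
#'
#' @slot reports data.frame with one row per category: \code{category},
#'   \code{n}, \code{meanE}, \code{worstE}, \code{clippedWorst},
#'   \code{wAvg}, \code{wWorst}, \code{contribution}.
#' @slot deviates named list of absolute deviates per category.
#' @slot meanLJ numeric(1), mean normalized LJ energy over nonbond pairs.
#' @slot wE numeric(1).
#' @export
setClass("WEScore",
  representation(
    reports = "data.frame",
    deviates = "list",
    meanLJ = "numeric",
    wE = "numeric"
  )
)

setValidity("WEScore", function(object) {
  r <- object@reports
  if (nrow(r)) {
    act <- r[r$n > 0, , drop = FALSE]
    if (nrow(act)) {
      if (any(act$wAvg < -1e-12 | act$wAvg > 1 + 1e-12))
        return("wAvg must lie in [0, 1]")
      if (any(act$wWorst < -1e-12 | act$wWorst > 1 + 1e-12))
        return("wWorst must lie in [0, 1]")
      if (any(act$clippedWorst > act$worstE + 1e-9))
        return("clip(E) must not exceed E")
      if (any(act$contribution < -1e-9))
        return("category contributions must be non-negative")
    }
  }
  if (object@wE < -1 - 1e-9)
    return("wE cannot be below -1 (only mean LJ can be negative)")
  TRUE
})

#' UntangleLedger: record of attempted swap/maneuver moves
#'
#' @slot moves data.frame with one row per attempted move: \code{move}
#'   (label), \code{wEBefore}, \code{wEAfter}, \code{densBefore},
#'   \code{densAfter}, \code{accepted}.
#' @export
setClass("UntangleLedger",
  representation(moves = "data.frame")
)

setValidity("UntangleLedger", function(object) {
  m <- object@moves
  if (nrow(m)) {
    need <- c("move", "wEBefore", "wEAfter", "densBefore", "densAfter",
              "accepted")
    if (!all(need %in% names(m)))
      return("moves is missing required columns")
    acc <- m[m$accepted, , drop = FALSE]
    if (nrow(acc) && any(acc$wEAfter >= acc$wEBefore + 1e-12))
      return("accepted moves must strictly decrease wE")
  }
  TRUE
})
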