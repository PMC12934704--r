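#' @include AllClasses.R
NULL

#' Accessors for EnsembleModel, DensityGrid, WEScore and UntangleLedger
#'
#' @param object,x an object of the corresponding class.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("bonds", function(object) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setGeneric("conformerLetters",
           function(object) standardGeneric("conformerLetters"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("coords<-", function(object, value) standardGeneric("coords<-"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("sigmaLevel", function(object) standardGeneric("sigmaLevel"))
#' @rdname accessors
#' @export
setGeneric("wE", function(object) standardGeneric("wE"))
#' @rdname accessors
#' @export
setGeneric("meanLJ", function(object) standardGeneric("meanLJ"))
#' @rdname accessors
#' @export
setGeneric("categoryReports", function(object) standardGeneric("categoryReports"))
#' @rdname accessors
#' @export
setGeneric("moves", function(object) standardGeneric("moves"))

#' @rdname accessors
#' @export
setMethod("atoms", "EnsembleModel", function(object) object@atoms)
#' @rdname accessors
#' @export
setMethod("bonds", "EnsembleModel", function(object) object@bonds)
#' @rdname accessors
#' @export
setMethod("conformerLetters", "EnsembleModel",
          function(object) object@conformerLetters)
#' @rdname accessors
#' @export
setMethod("nAtoms", "EnsembleModel", function(object) nrow(object@atoms))
#' @rdname accessors
#' @export
setMethod("coords", "EnsembleModel", function(object) {
  as.matrix(object@atoms[, c("x", "y", "z")])
})
#' @rdname accessors
#' @export
setMethod("coords<-", "EnsembleModel", function(object, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(object@atoms),
            ncol(value) == 3)
  object@atoms$x <- value[, 1]
  object@atoms$y <- value[, 2]
  object@atoms$z <- value[, 3]
  object
})

#' @rdname accessors
#' @export
setMethod("gridOrigin", "DensityGrid", function(object) object@origin)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "DensityGrid", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("gridValues", "DensityGrid", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("sigmaLevel", "DensityGrid", function(object) {
  v <- as.numeric(object@values)
  sqrt(mean((v - mean(v))^2))
})

#' @rdname accessors
#' @export
setMethod("wE", "WEScore", function(object) object@wE)
#' @rdname accessors
#' @export
setMethod("meanLJ", "WEScore", function(object) object@meanLJ)
#' @rdname accessors
#' @export
setMethod("categoryReports", "WEScore", function(object) object@reports)
#' @rdname accessors
#' @export
setMethod("moves", "UntangleLedger", function(object) object@moves)

setMethod("show", "EnsembleModel", function(object) {
  a <- object@atoms
  sg <- splitGroups(object)
  cat("EnsembleModel:", nrow(a), "sites,",
      length(unique(residueKeys(object))), "residues,",
      nrow(sg), "split groups\n")
  cat("  conformer letters:",
      paste(object@conformerLetters, collapse = ", "), "\n")
  cat("  bonds:", nrow(object@bonds),
      sprintf("(%d disulfide)", sum(object@bonds$kind == "ss")), "\n")
})

setMethod("show", "RestraintSet", function(object) {
  cat("RestraintSet:",
      nrow(object@bonds), "bonds,",
      nrow(object@angles), "angles,",
      nrow(object@torsions), "torsions,",
      nrow(object@nonbond), "nonbond pairs\n")
})

setMethod("show", "DensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("DensityGrid: %d x %d x %d voxels, spacing %.3f A\n",
              d[1], d[2], d[3], object@spacing))
  cat(sprintf("  origin (%.2f, %.2f, %.2f), sigma level %.4g\n",
              object@origin[1], object@origin[2], object@origin[3],
              sigmaLevel(object)))
})

setMethod("show", "WEScore", function(object) {
  cat(sprintf("WEScore: wE = %.4f (mean LJ = %.4f)\n",
              object@wE, object@meanLJ))
  r <- object@reports[object@reports$n > 0, , drop = FALSE]
  if (nrow(r)) {
    cat("  active categories:\n")
    for (i in seq_len(nrow(r))) {
      cat(sprintf(
        "   %-12s n=%4d  <E>=%8.3f  max(E)=%8.3f  wAvg=%.3f  wWorst=%.3f  contrib=%8.3f\n",
        r$category[i], r$n[i], r$meanE[i], r$worstE[i], r$wAvg[i],
        r$wWorst[i], r$contribution[i]))
    }
  }
})

setMethod("show", "UntangleLedger", function(object) {
  m <- object@moves
  cat("UntangleLedger:", nrow(m), "attempted moves,",
      sum(m$accepted), "accepted\n")
})
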