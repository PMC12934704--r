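#' @include AllClasses.R
NULL

# Atom and residue key helpers. Keys are plain strings so they can be used
# as names, JSON keys and data.frame cells.

makeAtomKeys <- function(a) {
  paste(a$chain, a$resno, a$ins, a$resname, a$name, sep = "|")
}

makeResidueKeys <- function(a) {
  paste(a$chain, a$resno, a$ins, a$resname, sep = "|")
}

#' Atom and residue keys of a model
#'
#' An atom key is \code{chain|resno|ins|resname|name}; the residue key drops
#' the trailing atom name. Split sites of the same atom share one atom key.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @return character vector, one entry per site.
#' @export
atomKeys <- function(model) makeAtomKeys(model@atoms)

#' @rdname atomKeys
#' @export
residueKeys <- function(model) makeResidueKeys(model@atoms)

# Standard-normal element electron counts used as Gaussian amplitudes.
elementWeight <- function(element) {
  w <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15)
  out <- unname(w[toupper(element)])
  out[is.na(out)] <- 6
  out
}

guessElement <- function(name) {
  # first alphabetic character of the stripped atom name, S for SG/SD etc.
  nm <- toupper(gsub("[^A-Z]", "", name))
  el <- substr(nm, 1, 1)
  el[nm %in% c("SG", "SD", "S")] <- "S"
  el[el == ""] <- "C"
  el
}

wrapAngle <- function(x) {
  # wrap degrees to (-180, 180]
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y[y <= -180] <- y[y <= -180] + 360
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
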