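#' @include restraints.R
NULL

#' Clip plateau for large statistical energies
#'
#' Identity up to E = 10; beyond the knee the energy grows
#' logarithmically, 10 + log(1 + (E - 10)), so a single extreme outlier
#' cannot overwhelm salvageable defects elsewhere: reducing a 6-sigma
#' deviate to 3 sigma is favorable even when it pushes a 20-sigma outlier
#' to 20.4 sigma.
#'
#' @param E non-negative statistical energies.
#' @return clipped energies (monotone, continuous, derivative <= 1 beyond
#'   the knee).
#' @export
clipEnergy <- function(E) {
  if (any(E < 0)) stopf("statistical energies must be non-negative")
  out <- E
  big <- E > 10
  out[big] <- 10 + log1p(E[big] - 10)
  out
}

#' Worst-outlier weight
#'
#' The probability that the largest of n independent standard-normal
#' deviate magnitudes stays below d: (2 Phi(d) - 1)^n. A 6-sigma worst
#' deviate among 100 terms is certainly not noise (weight 1); a 1-sigma
#' worst deviate is (weight 0).
#'
#' @param d non-negative worst deviate magnitude.
#' @param n number of deviates in the category (>= 1).
#' @return weight in [0, 1]; increasing in d, decreasing in n.
#' @export
softPnn <- function(d, n) {
  stopifnot(all(d >= 0), all(n >= 1))
  (2 * pnorm(d) - 1)^n
}

#' Chi-square weight on a category's average energy
#'
#' The cumulative probability of the chi-square distribution with n degrees
#' of freedom at the observed sum of squared deviates. A distribution far
#' broader than the library sigmas predict weighs in at 1, one far better
#' at 0; an exactly-as-expected distribution (sum at the chi-square median)
#' gets weight 0.5.
#'
#' @param deviates numeric vector of deviates (signs ignored).
#' @return weight in [0, 1].
#' @export
chi2Weight <- function(deviates) {
  n <- length(deviates)
  if (n < 1) return(NA_real_)
  pchisq(sum(deviates^2), df = n)
}

#' Equivalent sigma deviate of a probability
#'
#' Converts a probability-based score (rotamer or Ramachandran
#' probability p) to the standard-normal deviate whose two-sided tail
#' probability equals p.
#'
#' @param p probability in (0, 1].
#' @return non-negative deviate.
#' @export
probToDeviate <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  qnorm(1 - p / 2)
}

# The fixed 11-category roster; nonbond is scored as mean LJ energy.
weCategories <- c("bond", "angle", "torsion", "planarity", "chirality",
                  "omega", "cbeta", "rotamer", "ramachandran", "clash")

#' The weighted-energy (wE) score of a model
#'
#' Each validation category contributes its chi-square-weighted mean
#' statistical energy plus its worst-outlier-weighted clipped maximum
#' energy; the mean normalized Lennard-Jones energy over all nonbond pairs
#' is added unweighted and unclipped:
#' \deqn{wE = \sum_{cat} [\chi^2 \langle E\rangle +
#'   softPnn\, clip(max E)] + \langle E_{LJ}\rangle}
#' Empty categories contribute zero. Severe outliers saturate near the
#' clip knee, so wE tends to be about ten times the number of categories
#' carrying severe outliers.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param restraints optional prebuilt \linkS4class{RestraintSet}.
#' @param library restraint library used when \code{restraints} is missing.
#' @param extraDeviates optional named list of additional absolute deviates
#'   to merge into categories (e.g. externally computed rotamer deviates).
#' @return a \linkS4class{WEScore}.
#' @export
weScore <- function(model, restraints = NULL, library = NULL,
                    extraDeviates = NULL) {
  if (is.null(restraints)) restraints <- buildRestraints(model, library)
  devs <- categoryDeviates(model, restraints)
  if (!is.null(extraDeviates))
    for (nm in names(extraDeviates))
      devs[[nm]] <- c(devs[[nm]], abs(extraDeviates[[nm]]))

  rep <- data.frame(category = weCategories, n = 0L, meanE = NA_real_,
                    worstE = NA_real_, clippedWorst = NA_real_,
                    wAvg = NA_real_, wWorst = NA_real_, contribution = 0,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(rep))) {
    d <- devs[[rep$category[r]]]
    if (!length(d)) next
    e <- d^2
    rep$n[r] <- length(d)
    rep$meanE[r] <- mean(e)
    rep$worstE[r] <- max(e)
    rep$clippedWorst[r] <- clipEnergy(max(e))
    rep$wAvg[r] <- chi2Weight(d)
    rep$wWorst[r] <- softPnn(max(d), length(d))
    rep$contribution[r] <- rep$wAvg[r] * rep$meanE[r] +
      rep$wWorst[r] * rep$clippedWorst[r]
  }
  lj <- as.numeric(ljEnergies(model, restraints))
  mlj <- if (length(lj)) mean(lj) else 0
  new("WEScore", reports = rep, deviates = devs, meanLJ = mlj,
      wE = sum(rep$contribution) + mlj)
}

#' Serialize a WEScore to a JSON-ready list
#'
#' @param score a \linkS4class{WEScore}.
#' @return a plain list with every intermediate quantity.
#' @export
weScoreReport <- function(score) {
  list(
    wE = score@wE,
    meanLJ = score@meanLJ,
    categories = score@reports
  )
}
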