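# Breed-composition arithmetic, heterosis, breed labelling, and the
# bull-mother eligibility rule.

#' Construct a breed composition
#'
#' Gene fractions of Holstein-Friesian (F), Jersey (J) and Ayrshire (A),
#' summing to 1.
#'
#' @param F,J,A Non-negative gene fractions.
#' @return Named numeric vector c(F=, J=, A=).
#' @export
breed_comp <- function(F = 0, J = 0, A = 0) {
  x <- c(F = F, J = J, A = A)
  stopifnot(all(x >= -1e-12), abs(sum(x) - 1) <= 1e-12)
  pmax(x, 0)
}

#' Gene fractions of progeny
#'
#' Midpoint rule: each parent transmits half its genome, so progeny fractions
#' are the elementwise mean of sire and dam fractions. Preserves the
#' sum-to-one invariant exactly.
#'
#' @param sire,dam Breed compositions.
#' @return Progeny breed composition.
#' @export
progeny_composition <- function(sire, dam) {
  (sire + dam) / 2
}

#' Expected breed-of-origin heterozygosity of progeny
#'
#' Probability that a random locus carries alleles of distinct breed origin:
#' 1 - sum_b sire_b * dam_b. Symmetric in its arguments; 1 for an F1 cross,
#' 0 for purebred matings.
#'
#' @param sire,dam Breed compositions.
#' @return Heterozygosity in \[0, 1\].
#' @export
heterozygosity <- function(sire, dam) {
  1 - sum(as.numeric(sire) * as.numeric(dam))
}

#' Heterosis deviation of crossbred performance
#'
#' Per-trait additive bonus: heterozygosity x heterosis fraction x parental
#' mean. Expressed in trait units; zero at zero heterozygosity.
#'
#' @param het Breed-of-origin heterozygosity in \[0, 1\].
#' @param parental_mean Trait vector of the parental mean phenotype.
#' @param fractions Per-trait heterosis fractions (proportion of parental mean
#'   at full heterozygosity).
#' @return Trait vector of heterosis deviations.
#' @export
heterosis_effect <- function(het, parental_mean, fractions) {
  stopifnot(het >= 0, het <= 1)
  as_trait_vector(het * as.numeric(fractions) * as.numeric(parental_mean))
}

#' Classify an animal's breed label from its composition
#'
#' An animal is labelled as breed b if its b fraction is at least the
#' threshold (default 7/8, the same purity bound as the bull-mother rule,
#' boundary inclusive); otherwise as the two-breed cross of its two largest
#' fractions if they jointly reach the threshold; otherwise "multi".
#'
#' @param comp Breed composition.
#' @param threshold Purity threshold (default 7/8).
#' @return One of "F", "J", "A", "FxJ", "FxA", "JxA", "multi".
#' @export
classify_breed <- function(comp, threshold = 7 / 8) {
  b <- breed_names()
  x <- as.numeric(comp)[seq_along(b)]
  top <- which.max(x)
  if (x[top] >= threshold - 1e-12) return(b[top])
  ord <- order(x, decreasing = TRUE)[1:2]
  if (sum(x[ord]) >= threshold - 1e-12) {
    pair <- sort(ord) # canonical order F, J, A
    return(paste0(b[pair[1]], "x", b[pair[2]]))
  }
  "multi"
}

#' Bull-mother eligibility
#'
#' A cow may become a bull mother only with at least 3 generations of
#' artificial-breeding male ancestors on the maternal side and at least
#' seven-eighths gene composition of a single breed.
#'
#' @param generations_ab Count of consecutive AB-sired maternal generations.
#' @param comp Breed composition.
#' @param min_generations AB-ancestry requirement (default 3).
#' @param threshold Purity requirement (default 7/8).
#' @return Logical.
#' @export
bull_mother_eligible <- function(generations_ab, comp,
                                 min_generations = 3, threshold = 7 / 8) {
  generations_ab >= min_generations &
    max(as.numeric(comp)) >= threshold - 1e-12
}
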