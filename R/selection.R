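# Economic index theory: breeding worth, index reliability, truncation
# selection across overlapping age classes, and per-trait selection responses.

#' Breeding worth of an animal
#'
#' The inner product of a trait EBV vector with the economic values:
#' the national selection index in NZ$ per cow.
#'
#' @param ebv Trait vector of estimated breeding values (canonical order).
#' @param v Economic values (default [default_economic_values()]).
#' @return Breeding worth in NZ$.
#' @export
breeding_worth <- function(ebv, v = default_economic_values()) {
  stopifnot(length(ebv) == 4L, length(v) == 4L)
  sum(as.numeric(ebv) * as.numeric(v))
}

#' SD of the aggregate genotype
#'
#' sqrt(v' G v) for a genetic covariance matrix G and economic values v.
#'
#' @param G 4x4 genetic covariance matrix (PSD).
#' @param v Economic values.
#' @return SD in NZ$.
#' @export
aggregate_sd <- function(G, v = default_economic_values()) {
  if (!is_psd(G)) stop("genetic covariance matrix is not positive semi-definite")
  sqrt(drop(as.numeric(v) %*% G %*% as.numeric(v)))
}

#' Reliability of a cow's index from repeated lactation records
#'
#' Repeated-records formula: n h2 / (1 + (n - 1) t) for n records,
#' heritability h2 and repeatability t. With no records the reliability is 0
#' (parent-average information is deliberately excluded).
#'
#' @param n_lactations Number of lactation records (integer >= 0).
#' @param h2 Heritability of the index trait, in (0, 1].
#' @param repeatability Repeatability, with h2 <= repeatability < 1.
#' @return Reliability in \[0, 1\].
#' @export
cow_reliability <- function(n_lactations, h2, repeatability) {
  stopifnot(n_lactations >= 0, h2 > 0, h2 <= repeatability, repeatability < 1)
  if (n_lactations == 0) return(0)
  n_lactations * h2 / (1 + (n_lactations - 1) * repeatability)
}

#' Reliability of a progeny-tested bull's index
#'
#' Half-sib progeny-test formula: n / (n + lambda) with
#' lambda = (4 - h2) / h2 for n daughters.
#'
#' @param n_daughters Number of first-crop daughters (integer >= 0).
#' @param h2 Heritability of the index trait.
#' @return Reliability in \[0, 1).
#' @export
bull_reliability <- function(n_daughters, h2) {
  stopifnot(n_daughters >= 0, h2 > 0, h2 < 1)
  lambda <- (4 - h2) / h2
  n_daughters / (n_daughters + lambda)
}

# internal: upper-tail intensity phi(z)/Phibar(z), stable in the far tail
norm_intensity <- function(z) {
  p <- stats::pnorm(z, lower.tail = FALSE)
  ifelse(p < 1e-14, z + 1 / pmax(z, 1), stats::dnorm(z) / p)
}

#' Truncation selection across age classes
#'
#' Finds the single merit threshold x* such that the expected number of
#' candidates above x*, summed over all classes (each normal with its own
#' mean and SD of estimated merit), equals `n_required`. Classes with zero SD
#' contribute all-or-nothing; exact ties at the threshold are split
#' proportionally.
#'
#' @param pools Data frame with columns `count`, `mean`, `sd` (one row per
#'   age class; NZ$ scale for means/SDs).
#' @param n_required Total number to select (may be fractional).
#' @param tol Absolute tolerance on the threshold (NZ$), default 1e-8.
#' @return List with `threshold`, and per-class vectors `selected` and
#'   `intensity` (standardized selection differential of the selected).
#' @export
truncate_across_classes <- function(pools, n_required, tol = 1e-8) {
  stopifnot(all(pools$count >= 0), all(pools$sd >= 0), n_required >= 0)
  total <- sum(pools$count)
  if (n_required > total + 1e-9)
    stop("n_required exceeds total candidates (", n_required, " > ", total, ")")
  if (n_required >= total - 1e-12) {
    return(list(threshold = -Inf, selected = pools$count,
                intensity = rep(0, nrow(pools))))
  }
  frac_above <- function(x) {
    ifelse(pools$sd > 0,
           stats::pnorm((x - pools$mean) / pmax(pools$sd, 1e-300),
                        lower.tail = FALSE),
           as.numeric(pools$mean > x))
  }
  span <- max(pools$sd, 1)
  lo <- min(pools$mean) - 10 * span
  hi <- max(pools$mean) + 10 * span
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sum(pools$count * frac_above(mid)) > n_required) lo <- mid else hi <- mid
  }
  x <- (lo + hi) / 2
  fa <- frac_above(x)
  selected <- pools$count * fa
  # zero-SD classes sitting at the threshold are all-or-nothing in the
  # bisection; resolve them by proportional tie-splitting of the remainder
  tied <- pools$sd == 0 & abs(pools$mean - x) <= 10 * tol
  if (any(tied)) {
    selected[tied] <- 0
    remainder <- n_required - sum(selected)
    if (remainder > 0) {
      selected[tied] <- pmin(
        remainder * pools$count[tied] / sum(pools$count[tied]),
        pools$count[tied])
    }
    fa <- selected / pmax(pools$count, 1e-300)
  }
  z <- ifelse(pools$sd > 0, (x - pools$mean) / pmax(pools$sd, 1e-300), NA_real_)
  intensity <- ifelse(pools$sd > 0 & fa > 0, norm_intensity(z), 0)
  intensity[!is.finite(intensity)] <- 0
  list(threshold = x, selected = selected, intensity = intensity)
}

#' Per-trait response to one round of index selection
#'
#' Regression of trait values on the selection index: the response in trait j
#' is i sqrt(r) (G v)_j / sigma_T, and the response in the aggregate genotype
#' is i sqrt(r) sigma_T, for selection intensity i and index reliability r.
#'
#' @param intensity Standardized selection intensity (>= 0 for selection).
#' @param reliability Index reliability (squared correlation with T).
#' @param G Genetic covariance matrix.
#' @param v Economic values.
#' @return Named trait vector of expected genetic superiorities of the
#'   selected group, with attribute `aggregate` (NZ$).
#' @export
selection_response <- function(intensity, reliability, G,
                               v = default_economic_values()) {
  stopifnot(reliability >= 0, reliability <= 1)
  sigma_T <- aggregate_sd(G, v)
  resp <- intensity * sqrt(reliability) * drop(G %*% as.numeric(v)) / sigma_T
  resp <- as_trait_vector(resp)
  attr(resp, "aggregate") <- intensity * sqrt(reliability) * sigma_T
  resp
}

#' Annual genetic gain from selection pathways
#'
#' Rendel-Robertson aggregation: the sum of pathway genetic superiorities
#' divided by the sum of pathway generation intervals. Pathways with zero
#' selection differential (the cow-to-cow pathway) contribute nothing to the
#' numerator but their interval counts in the denominator.
#'
#' @param responses List of per-pathway trait vectors (or scalars).
#' @param intervals Numeric vector of pathway generation intervals (years).
#' @return Annual genetic gain per trait (or scalar), units per year.
#' @export
pathway_contribution <- function(responses, intervals) {
  stopifnot(length(responses) >= 1, length(responses) == length(intervals),
            all(intervals > 0))
  Reduce(`+`, responses) / sum(intervals)
}
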