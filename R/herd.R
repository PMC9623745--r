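# Age-structured cow demography, herd growth, and the progeny-test bull
# pipeline. Cohorts are data frames; counts are continuous (the model is
# deterministic, not agent-based).

#' Create cow cohorts
#'
#' @param age Integer vector of ages (years).
#' @param count Cow counts (continuous).
#' @param comp Matrix (rows = cohorts) or single composition of gene fractions.
#' @param gen_ab AB-ancestry generation count (capped at 3 for state purposes).
#' @param last_sire Breed of the cohort's sires ("F", "J", "A" or "none").
#' @param het Breed-of-origin heterozygosity of the cohort itself.
#' @param merit Matrix (rows = cohorts) or single trait vector of true genetic
#'   merit, as deviation from the 1996 national reference (breed base
#'   included).
#' @return Data frame of cow cohorts.
#' @export
cow_cohorts <- function(age, count, comp, gen_ab = 3, last_sire = "none",
                        het = 0, merit = trait_vector()) {
  n <- length(age)
  if (!is.matrix(comp)) comp <- matrix(comp, n, 3, byrow = TRUE)
  if (!is.matrix(merit)) merit <- matrix(merit, n, 4, byrow = TRUE)
  data.frame(
    age = age, count = count,
    fF = comp[, 1], fJ = comp[, 2], fA = comp[, 3],
    gen_ab = pmin(rep_len(gen_ab, n), 3L),
    last_sire = rep_len(last_sire, n),
    het = rep_len(het, n),
    milk = merit[, 1], fat = merit[, 2], protein = merit[, 3],
    liveweight = merit[, 4],
    stringsAsFactors = FALSE
  )
}

# internal: per-cohort breed labels
cohort_labels <- function(cows, threshold = 7 / 8) {
  vapply(seq_len(nrow(cows)), function(i) {
    classify_breed(c(cows$fF[i], cows$fJ[i], cows$fA[i]), threshold)
  }, character(1))
}

# internal: per-cohort breeding worth (true = estimated at cohort level)
cohort_bw <- function(cows, v) {
  as.numeric(as.matrix(cows[, trait_names()]) %*% as.numeric(v))
}

#' Equilibrium age structure
#'
#' Stable age distribution proportional to cumulative survival: the fraction
#' in age class k is prod(survival up to k) normalized to sum to one.
#'
#' @param survival Per-age survival proportions (probability of surviving from
#'   each class to the next; the last entry is not used), or a scalar applied
#'   to all classes.
#' @param n_ages Number of age classes (required when `survival` is scalar).
#' @return Vector of age-class fractions summing to 1.
#' @export
equilibrium_age_structure <- function(survival, n_ages = length(survival)) {
  if (length(survival) == 1) survival <- rep(survival, n_ages)
  stopifnot(all(survival >= 0), all(survival <= 1), n_ages >= 1)
  if (all(survival == 0)) stop("all-zero survival: no stable age structure")
  w <- cumprod(c(1, survival[seq_len(n_ages - 1)]))
  w / sum(w)
}

#' Herd growth
#'
#' Geometric growth: one year multiplies total cow places by (1 + rate).
#'
#' @param total_cows Current total (>= 0).
#' @param rate Annual growth rate (> -1).
#' @return New total.
#' @export
grow_herd <- function(total_cows, rate) {
  stopifnot(total_cows >= 0)
  if (rate <= -1) stop("growth rate must exceed -1")
  total_cows * (1 + rate)
}

#' Age cow cohorts by one year
#'
#' Applies survival, drops the oldest class, and admits replacements at the
#' youngest age. Replacement count is the balancing item: entrant weights are
#' rescaled so the new total equals `target_total`.
#'
#' @param cows Cow cohort data frame.
#' @param survival Annual survival proportion (scalar).
#' @param max_age Oldest cow age class (exits after this age).
#' @param entrants Data frame of replacement cohorts (same columns as `cows`,
#'   age ignored) whose `count` column is a set of relative weights, or NULL.
#' @param target_total Required total cow count after aging.
#' @param entry_age Age at which replacements enter (default 2).
#' @return List with `cows` (new cohort table) and `replacements` (count).
#' @export
age_cow_cohorts <- function(cows, survival, max_age, entrants, target_total,
                            entry_age = 2) {
  survivors <- cows
  survivors$count <- survivors$count * survival
  survivors$age <- survivors$age + 1L
  survivors <- survivors[survivors$age <= max_age, , drop = FALSE]
  n_rep <- target_total - sum(survivors$count)
  if (n_rep < -1e-6) stop("herd target below survivor count: cannot shrink by culling replacements only")
  n_rep <- max(n_rep, 0)
  if (is.null(entrants) || nrow(entrants) == 0 || sum(entrants$count) <= 0) {
    if (n_rep > 1e-6) stop("replacements required but none available")
    new_cows <- survivors
  } else {
    entrants$count <- entrants$count * n_rep / sum(entrants$count)
    entrants$age <- entry_age
    new_cows <- rbind(survivors, entrants[entrants$count > 0, , drop = FALSE])
  }
  rownames(new_cows) <- NULL
  list(cows = new_cows, replacements = n_rep)
}

#' Create bull cohorts
#'
#' @param breed Breed of the cohort ("F", "J", "A").
#' @param age Age in years (1-10).
#' @param live Count of live bulls.
#' @param dead_semen Count of dead proven bulls with stored semen (usable in
#'   the bull-dam pathway only).
#' @param merit Matrix or single trait vector of true genetic merit.
#' @param reliability Index reliability of the cohort's evaluations.
#' @return Data frame of bull cohorts.
#' @export
bull_cohorts <- function(breed, age, live, dead_semen = 0,
                         merit = trait_vector(), reliability = 0) {
  n <- length(age)
  if (!is.matrix(merit)) merit <- matrix(merit, n, 4, byrow = TRUE)
  data.frame(
    breed = rep_len(breed, n), age = age,
    live = live, dead_semen = rep_len(dead_semen, n),
    milk = merit[, 1], fat = merit[, 2], protein = merit[, 3],
    liveweight = merit[, 4],
    reliability = rep_len(reliability, n),
    stringsAsFactors = FALSE
  )
}

#' Advance the bull pipeline by one year
#'
#' Ages all bull cohorts, applies survival (deaths of proven bulls accrue to
#' the dead-with-semen pool), drops bulls past age 10, assigns the
#' progeny-test reliability when a cohort reaches proving age, and admits the
#' entering young cohorts at age 1.
#'
#' @param bulls Bull cohort data frame.
#' @param young Data frame of entering age-1 cohorts (as [bull_cohorts()]),
#'   or NULL.
#' @param demography Demography parameter list (see [default_demography()]).
#' @param h2_index Heritability of the index, for the progeny-test
#'   reliability.
#' @return New bull cohort data frame.
#' @export
bull_pipeline_step <- function(bulls, young, demography, h2_index) {
  b <- bulls
  if (nrow(b)) {
    deaths <- b$live * (1 - demography$bull_survival)
    proven <- b$age >= demography$proving_age
    b$dead_semen <- b$dead_semen + ifelse(proven, deaths, 0)
    b$live <- b$live - deaths
    b$age <- b$age + 1L
    newly_proven <- b$age == demography$proving_age
    b$reliability[newly_proven] <-
      bull_reliability(demography$daughters_per_bull, h2_index)
    b <- b[b$age <= 10L, , drop = FALSE]
  }
  if (!is.null(young) && nrow(young)) {
    young$age <- 1L
    b <- rbind(b, young)
  }
  rownames(b) <- NULL
  b
}
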