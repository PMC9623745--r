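# The nine national mating strategies, bull-team selection, and bull-mother
# selection. All allocation is deterministic and cohort-level.

# internal: majority breed of each cohort (ties broken in F, J, A order)
majority_breed <- function(cows) {
  breed_names()[max.col(as.matrix(cows[, c("fF", "fJ", "fA")]),
                        ties.method = "first")]
}

# internal: rotation sire for one cohort
rotation_sire <- function(last_sire, comp, rotation) {
  if (last_sire %in% rotation) {
    i <- match(last_sire, rotation)
    return(rotation[i %% length(rotation) + 1L])
  }
  # foundation cows: start with the rotation breed of minority gene fraction
  fr <- comp[match(rotation, breed_names())]
  rotation[which.min(fr)]
}

#' Select bull teams for one breed
#'
#' Bull-dam team: the `dam_team_size` best proven bulls at team ages by
#' estimated breeding worth, dead or alive (stored semen is usable for
#' contract matings). Commercial team: the top `n_commercial` live proven
#' bulls at team ages. Team merit includes the within-cohort selection
#' differential from picking the best bulls on their estimated proofs.
#'
#' @param bulls Bull cohort data frame (single breed).
#' @param demography Demography parameters.
#' @param econ Economic values.
#' @param G Genetic covariance matrix.
#' @param n_commercial Number of live bulls needed for commercial matings.
#' @return List with `dam_team` and `comm_team`, each a list(merit, bw, n),
#'   or NULL entries when no proven bulls exist.
#' @export
select_bull_team <- function(bulls, demography, econ, G, n_commercial) {
  at_age <- bulls[bulls$age %in% demography$team_ages, , drop = FALSE]
  if (!nrow(at_age)) return(list(dam_team = NULL, comm_team = NULL))
  sigma_T <- aggregate_sd(G, econ)
  merit_mat <- as.matrix(at_age[, trait_names()])
  bw <- as.numeric(merit_mat %*% as.numeric(econ))
  pick <- function(counts, n) {
    n <- min(n, sum(counts))
    if (n <= 0) return(NULL)
    pools <- data.frame(count = counts, mean = bw,
                        sd = sqrt(at_age$reliability) * sigma_T)
    # deterministic tie-break: bisection threshold is tie-free for distinct
    # means; equal-mean cohorts share proportionally (age ascending in table)
    sel <- truncate_across_classes(pools, n)
    w <- sel$selected / sum(sel$selected)
    merit <- trait_vector()
    for (k in seq_len(nrow(at_age))) {
      if (w[k] <= 0) next
      resp <- selection_response(sel$intensity[k], at_age$reliability[k], G, econ)
      merit <- merit + w[k] * (merit_mat[k, ] + as.numeric(resp))
    }
    list(merit = as_trait_vector(merit),
         bw = breeding_worth(merit, econ), n = n)
  }
  list(dam_team = pick(at_age$live + at_age$dead_semen, demography$dam_team_size),
       comm_team = pick(at_age$live, n_commercial))
}

#' Select bull mothers within a breed
#'
#' Truncation selection on estimated breeding worth over the eligible cow
#' cohorts of one breed (at least 3 generations of AB ancestry and at least
#' 7/8 gene composition of the breed). If demand exceeds the eligible pool,
#' all eligible cows are selected with a warning.
#'
#' @param cows Cow cohort data frame.
#' @param n_needed Number of contract matings required.
#' @param breed Breed ("F", "J" or "A").
#' @param genetics Genetic parameter list.
#' @param econ Economic values.
#' @param label_threshold Purity threshold (default 7/8).
#' @return List(merit, bw, n_selected) of the dam team, or NULL when no
#'   eligible cows exist.
#' @export
select_bull_mothers <- function(cows, n_needed, breed, genetics, econ,
                                label_threshold = 7 / 8) {
  fr <- cows[[paste0("f", breed)]]
  elig <- fr >= label_threshold - 1e-12 & cows$gen_ab >= 3
  if (!any(elig)) {
    warning("no eligible bull mothers for breed ", breed)
    return(NULL)
  }
  cand <- cows[elig, , drop = FALSE]
  sigma_T <- aggregate_sd(genetics$G, econ)
  rel <- vapply(cand$age, function(a) {
    cow_reliability(max(a - 1, 0), genetics$h2_index, genetics$repeatability_index)
  }, numeric(1))
  bw <- cohort_bw(cand, econ)
  n <- min(n_needed, sum(cand$count))
  if (n < n_needed) warning("bull-mother demand exceeds eligible cows for breed ", breed)
  sel <- truncate_across_classes(
    data.frame(count = cand$count, mean = bw, sd = sqrt(rel) * sigma_T), n)
  w <- sel$selected / sum(sel$selected)
  merit_mat <- as.matrix(cand[, trait_names()])
  merit <- trait_vector()
  for (k in seq_len(nrow(cand))) {
    if (w[k] <= 0) next
    resp <- selection_response(sel$intensity[k], rel[k], genetics$G, econ)
    merit <- merit + w[k] * (merit_mat[k, ] + as.numeric(resp))
  }
  list(merit = as_trait_vector(merit), bw = breeding_worth(merit, econ),
       n_selected = n)
}

#' Allocate matings under a national strategy
#'
#' Straightbred floors are satisfied first (within-breed AB matings of the
#' highest-worth straightbred cows). Of the remaining cows in each cohort, the
#' AB fraction is mated per the strategy (capacity-capped by each breed's live
#' proven bulls times doses per bull, scarce semen going to the
#' highest-breeding-worth cohorts first, spillover to the cohort's own
#' majority breed), and the rest are mated to unselected natural-service
#' bulls of the cohort's own composition.
#'
#' @param cows Cow cohort data frame.
#' @param strategy One of [strategy_names()].
#' @param capacity Named vector (F, J, A) of AB mating capacity.
#' @param best_breed Breed ranked highest on team breeding worth (used by
#'   `best_bulls`).
#' @param config Simulation configuration.
#' @return Data frame with columns `cohort` (row of `cows`), `sire` ("F",
#'   "J", "A" or "natural") and `matings`; attribute `floor_matings` gives
#'   per-breed floor allocations.
#' @export
allocate_matings <- function(cows, strategy, capacity, best_breed, config) {
  stopifnot(strategy %in% strategy_names())
  d <- config$demography
  v <- config$economic_values
  labels <- cohort_labels(cows, config$label_threshold)
  bw <- cohort_bw(cows, v)
  maj <- majority_breed(cows)
  remaining <- cows$count
  cap <- capacity
  out_cohort <- integer(0); out_sire <- character(0); out_n <- numeric(0)
  emit <- function(i, sire, m) {
    if (m <= 1e-9) return(invisible())
    out_cohort <<- c(out_cohort, i); out_sire <<- c(out_sire, sire)
    out_n <<- c(out_n, m)
    invisible()
  }

  # straightbred floors first, best cows first, within-breed AB matings
  floor_used <- c(F = 0, J = 0, A = 0)
  for (b in breed_names()) {
    idx <- which(labels == b)
    if (!length(idx)) next
    need <- min(d$straightbred_floor, sum(remaining[idx]))
    if (need < d$straightbred_floor)
      warning("straightbred floor infeasible for breed ", b,
              ": only ", round(sum(remaining[idx])), " cows")
    for (i in idx[order(bw[idx], decreasing = TRUE)]) {
      if (need <= 1e-9) break
      m <- min(remaining[i], need, cap[b])
      emit(i, b, m)
      remaining[i] <- remaining[i] - m
      cap[b] <- cap[b] - m
      need <- need - m
      floor_used[b] <- floor_used[b] + m
    }
  }

  rotation <- switch(strategy,
    rot_FJ = c("F", "J"), rot_FA = c("F", "A"), rot_JA = c("J", "A"),
    rot_FJA = c("F", "J", "A"), NULL)

  # commercial AB matings, highest-worth cohorts first
  for (i in order(bw, decreasing = TRUE)) {
    ab <- remaining[i] * d$ab_fraction
    nat <- remaining[i] - ab
    remaining[i] <- 0
    target <- switch(strategy,
      # straightbreeding keeps crossbred pools closed: no crossbred bull
      # teams exist, so non-pure labels breed within their own pool
      straight = if (labels[i] %in% breed_names()) maj[i] else "natural",
      upgrade_F = "F", upgrade_J = "J", upgrade_A = "A",
      best_bulls = best_breed,
      rotation_sire(cows$last_sire[i], c(cows$fF[i], cows$fJ[i], cows$fA[i]),
                    rotation))
    if (identical(target, "natural")) {
      nat <- nat + ab
      ab <- 0
    } else {
      for (s in unique(c(target, maj[i]))) {
        m <- min(ab, cap[s])
        emit(i, s, m)
        cap[s] <- cap[s] - m
        ab <- ab - m
        if (ab <= 1e-9) break
      }
    }
    emit(i, "natural", nat + ab) # unmet AB demand reverts to natural service
  }
  plan <- data.frame(cohort = out_cohort, sire = out_sire, matings = out_n,
                     stringsAsFactors = FALSE)
  attr(plan, "floor_matings") <- floor_used
  plan
}
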