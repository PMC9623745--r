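# Orchestrates the annual cycle: bull teams -> bull mothers -> mating
# allocation -> progeny cohorts -> bull pipeline -> cow aging under herd
# growth -> annual summary. Fully deterministic.

# internal: count-weighted mean trait matrix rows
weighted_merit <- function(mat, w) {
  if (sum(w) <= 0) return(trait_vector())
  as_trait_vector(colSums(mat * w) / sum(w))
}

#' Initialize the base population
#'
#' Builds the start-year state: label shares over purebred F, J, A and F1
#' F x J cohorts, equilibrium age structure, base breed merits, and a bull
#' pipeline at the steady state implied by zero prior selection (so the first
#' years of a run show rising gain while the pipeline fills). The first two
#' replacement crops (matings that predate the simulation) reproduce the base
#' label mix.
#'
#' @param config A `herdsim_config`.
#' @return Object of class `herdsim_state`.
#' @export
initialize_base_population <- function(config) {
  g <- config$genetics
  d <- config$demography
  shares <- config$init$shares
  if (abs(sum(shares) - 1) > 1e-8) stop("initial shares must sum to 1")
  total <- config$init$total_cows
  ages <- d$cow_ages
  agefrac <- equilibrium_age_structure(d$cow_survival, length(ages))

  label_def <- list(
    F = list(comp = c(1, 0, 0), sire = "F"),
    J = list(comp = c(0, 1, 0), sire = "J"),
    A = list(comp = c(0, 0, 1), sire = "A"),
    FxJ = list(comp = c(0.5, 0.5, 0), sire = "none")
  )
  base_merit <- function(comp) as_trait_vector(drop(comp %*% g$base_means))
  cows <- NULL
  for (lab in names(shares)) {
    if (shares[[lab]] <= 0) next
    def <- label_def[[lab]]
    comp <- def$comp
    het0 <- 1 - sum(comp^2) # random-mating expectation within the pool
    cc <- cow_cohorts(
      age = ages, count = total * shares[[lab]] * agefrac,
      comp = matrix(comp, length(ages), 3, byrow = TRUE),
      gen_ab = 3, last_sire = def$sire, het = het0,
      merit = matrix(base_merit(comp), length(ages), 4, byrow = TRUE)
    )
    cows <- rbind(cows, cc)
  }

  # historical breed usage: straightbred matings plus half of each cross
  usage <- c(
    F = shares[["F"]] + 0.5 * shares[["FxJ"]],
    J = shares[["J"]] + 0.5 * shares[["FxJ"]],
    A = shares[["A"]]
  )
  rel_proven <- bull_reliability(d$daughters_per_bull, g$h2_index)
  bulls <- NULL
  for (b in breed_names()) {
    tested <- d$test_ratio *
      ceiling(usage[[b]] * total * d$ab_fraction / d$doses_per_bull)
    tested <- max(tested, d$test_ratio)
    comp <- c(F = 0, J = 0, A = 0); comp[b] <- 1
    bb <- bull_cohorts(
      breed = b, age = 1:10,
      live = tested * d$bull_survival^(0:9),
      dead_semen = pmax(tested * (d$bull_survival^(d$proving_age - 1) -
                                    d$bull_survival^(0:9)), 0),
      merit = matrix(base_merit(comp), 10, 4, byrow = TRUE),
      reliability = ifelse(1:10 >= d$proving_age, rel_proven, 0)
    )
    bulls <- rbind(bulls, bb)
  }

  # pre-simulation replacement crops: base label mix at base merit
  mk_pending <- function() {
    p <- NULL
    for (lab in names(shares)) {
      if (shares[[lab]] <= 0) next
      def <- label_def[[lab]]
      comp <- def$comp
      p <- rbind(p, cow_cohorts(
        age = min(ages), count = shares[[lab]],
        comp = matrix(comp, 1, 3, byrow = TRUE),
        gen_ab = 3, last_sire = def$sire, het = 1 - sum(comp^2),
        merit = matrix(base_merit(comp), 1, 4, byrow = TRUE)
      ))
    }
    p
  }
  # only the first aging step predates the first simulated mating plan
  pending <- list()
  pending[[as.character(config$start_year + 1)]] <- mk_pending()

  state <- list(year = config$start_year, cows = cows, bulls = bulls,
                pending = pending, base_total = total)
  class(state) <- "herdsim_state"
  state
}

# internal: population-mean merit of a breed's cows (no-selection teams)
population_team <- function(cows, breed, config) {
  fr <- cows[[paste0("f", breed)]]
  sel <- fr >= config$label_threshold - 1e-12
  if (!any(sel)) {
    comp <- c(F = 0, J = 0, A = 0); comp[breed] <- 1
    m <- as_trait_vector(drop(comp %*% config$genetics$base_means))
  } else {
    m <- weighted_merit(as.matrix(cows[sel, trait_names()]), cows$count[sel])
  }
  list(merit = m, bw = breeding_worth(m, config$economic_values))
}

#' Count-weighted phenotypic mean of the herd
#'
#' Per cohort and trait: (mature base phenotype + genetic merit deviation)
#' times the age-adjustment factor, plus the heterosis deviation
#' (heterozygosity x heterosis fraction x parental mean). No environmental
#' year effects are modelled.
#'
#' @param state A `herdsim_state`.
#' @param config A `herdsim_config`.
#' @return Named trait vector of phenotypic means per cow.
#' @export
phenotypic_mean <- function(state, config) {
  cows <- state$cows
  g <- config$genetics
  adj <- config$age_adjust[as.character(cows$age)]
  merit <- as.matrix(cows[, trait_names()])
  add <- sweep(merit, 2, g$phenotype_base, `+`)
  phen <- add * adj + add * (cows$het * matrix(g$heterosis, nrow(cows), 4,
                                               byrow = TRUE))
  weighted_merit(phen, cows$count)
}

# internal: one-year annual summary of a state
annual_summary <- function(state, config) {
  cows <- state$cows
  labels <- cohort_labels(cows, config$label_threshold)
  all_labels <- c("F", "J", "A", "FxJ", "FxA", "JxA", "multi")
  counts <- vapply(all_labels,
                   function(l) sum(cows$count[labels == l]), numeric(1))
  total <- sum(cows$count)
  gen <- weighted_merit(as.matrix(cows[, trait_names()]), cows$count)
  phen <- phenotypic_mean(state, config)
  out <- data.frame(
    year = state$year,
    milk = gen[["milk"]], fat = gen[["fat"]], protein = gen[["protein"]],
    liveweight = gen[["liveweight"]],
    bw = breeding_worth(gen, config$economic_values),
    phen_milk = phen[["milk"]], phen_fat = phen[["fat"]],
    phen_protein = phen[["protein"]], phen_liveweight = phen[["liveweight"]],
    total_cows = total
  )
  for (l in all_labels) {
    out[[paste0("share_", l)]] <- counts[[l]] / total
    out[[paste0("count_", l)]] <- counts[[l]]
  }
  out
}

#' Advance the simulation by one year
#'
#' Executes, in order: bull-team selection, bull-mother selection and young
#' bull entry, mating allocation (strategy plus straightbred floors), progeny
#' cohort creation (midparent merit, midpoint gene fractions, recorded
#' heterozygosity), bull pipeline update, and cow aging under herd growth.
#'
#' @param state A `herdsim_state`.
#' @param config A `herdsim_config`.
#' @return The new `herdsim_state` (one year later), with the new year's
#'   summary row attached as attribute `summary`.
#' @export
step_year <- function(state, config) {
  g <- config$genetics
  d <- config$demography
  v <- config$economic_values
  cows <- state$cows
  bulls <- state$bulls
  total <- sum(cows$count)
  sel_on <- isTRUE(config$selection_enabled)

  # AB capacity and a team-worth ranking per breed
  capacity <- c(F = 0, J = 0, A = 0)
  team_rank_bw <- c(F = -Inf, J = -Inf, A = -Inf)
  for (b in breed_names()) {
    bb <- bulls[bulls$breed == b & bulls$age %in% d$team_ages, , drop = FALSE]
    capacity[b] <- sum(bb$live) * d$doses_per_bull
    if (nrow(bb) && sum(bb$live) > 0) {
      if (sel_on) {
        team <- select_bull_team(bb, d, v, g$G, d$dam_team_size)$comm_team
        if (!is.null(team)) team_rank_bw[b] <- team$bw
      } else {
        team_rank_bw[b] <- population_team(cows, b, config)$bw
      }
    }
  }
  best_breed <- names(which.max(team_rank_bw))

  # mating allocation (floors first, then strategy)
  plan <- allocate_matings(cows, config$strategy, capacity, best_breed, config)
  demand <- vapply(breed_names(),
                   function(b) sum(plan$matings[plan$sire == b]), numeric(1))

  # commercial and bull-dam teams at realized demand
  teams <- list()
  for (b in breed_names()) {
    bb <- bulls[bulls$breed == b, , drop = FALSE]
    if (sel_on) {
      n_comm <- ceiling(demand[[b]] / d$doses_per_bull)
      teams[[b]] <- select_bull_team(bb, d, v, g$G, max(n_comm, 1))
    } else {
      pt <- population_team(cows, b, config)
      teams[[b]] <- list(dam_team = pt, comm_team = pt)
    }
  }

  # young bulls tested this year, sized to anticipated semen demand
  growth4 <- (1 + d$growth_rate)^4
  anticipated <- demand
  target_full <- d$ab_fraction * total * growth4
  if (config$strategy %in% c("upgrade_F", "upgrade_J", "upgrade_A")) {
    bx <- sub("upgrade_", "", config$strategy)
    anticipated[bx] <- target_full
  } else if (config$strategy == "best_bulls") {
    anticipated[best_breed] <- target_full
  } else if (grepl("^rot_", config$strategy)) {
    rot <- strsplit(sub("rot_", "", config$strategy), "")[[1]]
    anticipated[rot] <- pmax(anticipated[rot], target_full / length(rot))
  } else {
    anticipated <- anticipated * growth4
  }
  young <- NULL
  for (b in breed_names()) {
    tested <- d$test_ratio * ceiling(anticipated[[b]] / d$doses_per_bull)
    if (tested <= 0) next
    if (sel_on) {
      mothers <- suppressWarnings(select_bull_mothers(
        cows, d$contract_ratio * tested, b, g, v, config$label_threshold))
      dam_team <- teams[[b]]$dam_team
      if (is.null(mothers) || is.null(dam_team)) next
      merit <- (mothers$merit + dam_team$merit) / 2
    } else {
      merit <- population_team(cows, b, config)$merit
    }
    young <- rbind(young, bull_cohorts(breed = b, age = 1L, live = tested,
                                       merit = merit, reliability = 0))
  }

  # progeny cohorts from the mating plan
  comp_mat <- as.matrix(cows[, c("fF", "fJ", "fA")])
  merit_mat <- as.matrix(cows[, trait_names()])
  pr <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    i <- plan$cohort[k]
    s <- plan$sire[k]
    dam_comp <- comp_mat[i, ]
    dam_merit <- merit_mat[i, ]
    if (s == "natural") {
      sire_comp <- dam_comp
      sire_merit <- dam_merit
      gen_ab <- 0L
      last_sire <- "none"
    } else {
      sire_comp <- c(0, 0, 0); sire_comp[match(s, breed_names())] <- 1
      team <- teams[[s]]$comm_team
      sire_merit <- if (is.null(team)) {
        drop(sire_comp %*% g$base_means)
      } else as.numeric(team$merit)
      gen_ab <- min(cows$gen_ab[i] + 1L, 3L)
      last_sire <- s
    }
    pcomp <- (sire_comp + dam_comp) / 2
    pr[[k]] <- data.frame(
      count = plan$matings[k],
      fF = pcomp[1], fJ = pcomp[2], fA = pcomp[3],
      gen_ab = gen_ab, last_sire = last_sire,
      het = 1 - sum(sire_comp * dam_comp),
      milk = (sire_merit[1] + dam_merit[1]) / 2,
      fat = (sire_merit[2] + dam_merit[2]) / 2,
      protein = (sire_merit[3] + dam_merit[3]) / 2,
      liveweight = (sire_merit[4] + dam_merit[4]) / 2,
      stringsAsFactors = FALSE
    )
  }
  prog <- do.call(rbind, pr)
  # merge progeny sharing (label, AB generations, last sire): the cohort unit
  key <- paste(cohort_labels(prog, config$label_threshold),
               prog$gen_ab, prog$last_sire)
  merged <- lapply(split(prog, key), function(gd) {
    w <- gd$count
    out <- gd[1, , drop = FALSE]
    out$count <- sum(w)
    for (cl in c("fF", "fJ", "fA", "het", trait_names()))
      out[[cl]] <- sum(gd[[cl]] * w) / sum(w)
    out
  })
  prog <- do.call(rbind, merged)
  prog$age <- 2L
  rownames(prog) <- NULL

  # pipeline and demography updates
  bulls <- bull_pipeline_step(bulls, young, d, g$h2_index)
  new_year <- state$year + 1L
  target <- state$base_total * (1 + d$growth_rate)^(new_year - config$start_year)
  entrants <- state$pending[[as.character(new_year)]]
  aged <- age_cow_cohorts(cows, d$cow_survival, max(d$cow_ages), entrants,
                          target, entry_age = min(d$cow_ages))

  pending <- state$pending
  pending[[as.character(new_year)]] <- NULL
  pending[[as.character(state$year + 2L)]] <- prog[, colnames(cows)]

  new_state <- list(year = new_year, cows = aged$cows, bulls = bulls,
                    pending = pending, base_total = state$base_total)
  class(new_state) <- "herdsim_state"
  attr(new_state, "summary") <- annual_summary(new_state, config)
  new_state
}

#' Run the simulation
#'
#' Deterministic annual cycle from the start year to the end year; two runs
#' with identical configuration are bit-identical.
#'
#' @param config A `herdsim_config` (default [default_parameters()]).
#' @return Object of class `herdsim_result`: list with `summary` (one row per
#'   year), `final_state`, and `config`.
#' @export
run_simulation <- function(config = default_parameters()) {
  validate_config(config)
  state <- initialize_base_population(config)
  rows <- list(annual_summary(state, config))
  if (config$end_year > config$start_year) {
    for (y in seq_len(config$end_year - config$start_year)) {
      state <- step_year(state, config)
      rows[[y + 1]] <- attr(state, "summary")
    }
  }
  out <- list(summary = do.call(rbind, rows), final_state = state,
              config = config)
  class(out) <- "herdsim_result"
  out
}

#' @export
print.herdsim_result <- function(x, ...) {
  s <- x$summary
  last <- s[nrow(s), ]
  cat("herdsim run:", x$config$strategy, s$year[1], "-", last$year, "\n")
  cat(sprintf("  cows %s -> %s\n", format(round(s$total_cows[1]), big.mark = ","),
              format(round(last$total_cows), big.mark = ",")))
  cat(sprintf("  breeding worth %.1f -> %.1f NZ$\n", s$bw[1], last$bw))
  cat(sprintf("  %d shares: F %.0f%%  J %.0f%%  FxJ %.0f%%  A %.0f%%\n",
              last$year, 100 * last$share_F, 100 * last$share_J,
              100 * last$share_FxJ, 100 * last$share_A))
  invisible(x)
}

#' @export
print.herdsim_state <- function(x, ...) {
  cat("herdsim state, year", x$year, "\n")
  cat("  cow cohorts :", nrow(x$cows), " (",
      format(round(sum(x$cows$count)), big.mark = ","), "cows )\n")
  cat("  bull cohorts:", nrow(x$bulls), "\n")
  invisible(x)
}

#' Export the cohort table of a state as CSV
#'
#' One row per cow cohort (age, count, gene fractions, AB generations,
#' heterozygosity, merit, label).
#'
#' @param state A `herdsim_state`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohorts_csv <- function(state, path) {
  cows <- state$cows
  cows$label <- cohort_labels(cows)
  utils::write.csv(cows, path, row.names = FALSE)
  invisible(path)
}
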