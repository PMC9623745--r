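make_proven_bulls <- function(bws, live = 1, dead = 0, rel = 0) {
  # one single-bull cohort per entry, ages within the team window
  bull_cohorts(breed = "J", age = rep(5:7, length.out = length(bws)),
               live = rep_len(live, length(bws)),
               dead_semen = rep_len(dead, length(bws)),
               merit = cbind(0, 0, bws / 4.054, 0), # encode bw via protein
               reliability = rel)
}

test_that("commercial team is the top-n live proven bulls by worth", {
  d <- default_demography()
  v <- default_economic_values()
  G <- default_genetic_parameters()$G
  bulls <- make_proven_bulls(c(50, 90, 70, 30, 60))
  team <- select_bull_team(bulls, d, v, G, n_commercial = 2)$comm_team
  expect_equal(team$n, 2)
  expect_equal(team$bw, (90 + 70) / 2, tolerance = 1e-6)
})

test_that("dead proven bulls serve the bull-dam pathway only", {
  d <- default_demography()
  v <- default_economic_values()
  G <- default_genetic_parameters()$G
  bulls <- rbind(
    make_proven_bulls(c(40, 50, 60)),
    make_proven_bulls(100, live = 0, dead = 1) # dead, top merit
  )
  teams <- select_bull_team(bulls, d, v, G, n_commercial = 3)
  expect_equal(teams$dam_team$bw, (100 + 60 + 50) / 3, tolerance = 1e-6)
  expect_equal(teams$comm_team$bw, (40 + 50 + 60) / 3, tolerance = 1e-6)
})

test_that("team selection is deterministic under ties", {
  d <- default_demography()
  v <- default_economic_values()
  G <- default_genetic_parameters()$G
  bulls <- make_proven_bulls(c(80, 80, 20))
  t1 <- select_bull_team(bulls, d, v, G, 1)$comm_team
  t2 <- select_bull_team(bulls, d, v, G, 1)$comm_team
  expect_identical(t1, t2)
  expect_equal(t1$bw, 80, tolerance = 1e-6) # tied cohorts split evenly
})

test_that("bull mothers respect the eligibility mask and demand", {
  cfg <- default_parameters()
  cows <- rbind(
    cow_cohorts(age = c(3, 5), count = c(4000, 4000), comp = c(0, 1, 0),
                gen_ab = 3, merit = trait_vector(protein = 10)),
    cow_cohorts(age = 4, count = 4000, comp = c(0, 1, 0), gen_ab = 2),
    cow_cohorts(age = 4, count = 4000, comp = c(0.5, 0.5, 0), gen_ab = 3)
  )
  out <- select_bull_mothers(cows, 100 * 6.6, "J", cfg$genetics,
                             cfg$economic_values)
  expect_equal(out$n_selected, 660)
  # selected mothers beat the eligible-pool mean (positive differential)
  expect_gt(out$bw, breeding_worth(trait_vector(protein = 10)))
  # no eligible cohort at all: warning and NULL
  expect_warning(
    none <- select_bull_mothers(cows[3, ], 10, "J", cfg$genetics,
                                cfg$economic_values),
    "no eligible")
  expect_null(none)
})

test_that("straightbreeding mates every pool within itself", {
  cfg <- default_parameters("straight")
  state <- initialize_base_population(cfg)
  cap <- c(F = 1e9, J = 1e9, A = 1e9)
  plan <- allocate_matings(state$cows, "straight", cap, "J", cfg)
  labels <- herdsim:::cohort_labels(state$cows)
  for (k in seq_len(nrow(plan))) {
    lab <- labels[plan$cohort[k]]
    if (lab %in% breed_names()) {
      expect_true(plan$sire[k] %in% c(lab, "natural"))
    } else {
      expect_equal(plan$sire[k], "natural")
    }
  }
})

test_that("upgrading sends all commercial AB matings to the target breed", {
  cfg <- default_parameters("upgrade_J")
  state <- initialize_base_population(cfg)
  cap <- c(F = 1e9, J = 1e9, A = 1e9)
  plan <- allocate_matings(state$cows, "upgrade_J", cap, "J", cfg)
  floors <- attr(plan, "floor_matings")
  ab_frac <- cfg$demography$ab_fraction
  total <- sum(state$cows$count)
  j_matings <- sum(plan$matings[plan$sire == "J"])
  expected <- floors[["J"]] + (total - sum(floors)) * ab_frac
  expect_equal(j_matings, expected, tolerance = 1e-6)
  # an F purebred cohort crossed to J gives midpoint F1 progeny
  f1 <- progeny_composition(breed_comp(J = 1), breed_comp(F = 1))
  expect_equal(classify_breed(f1), "FxJ")
})

test_that("straightbred floors are satisfied before commercial allocation", {
  cfg <- default_parameters("best_bulls")
  state <- initialize_base_population(cfg)
  cap <- c(F = 1e9, J = 1e9, A = 1e9)
  plan <- allocate_matings(state$cows, "best_bulls", cap, "J", cfg)
  floors <- attr(plan, "floor_matings")
  expect_equal(unname(floors), rep(44000, 3))
  # floors go to the highest-worth straightbred cohorts, within breed
  labels <- herdsim:::cohort_labels(state$cows)
  for (b in breed_names()) {
    in_breed <- sum(plan$matings[plan$sire == b &
                                   labels[plan$cohort] == b])
    expect_gte(in_breed + 1e-6, 44000)
  }
})

test_that("floor infeasibility warns and mates all available", {
  cfg <- default_parameters("best_bulls")
  cfg$init$total_cows <- 10000
  state <- initialize_base_population(cfg)
  cap <- c(F = 1e9, J = 1e9, A = 1e9)
  msgs <- capture_warnings(
    plan <- allocate_matings(state$cows, "best_bulls", cap, "J", cfg))
  expect_true(any(grepl("floor infeasible", msgs)))
  labels <- herdsim:::cohort_labels(state$cows)
  a_cows <- sum(state$cows$count[labels == "A"])
  a_within <- sum(plan$matings[plan$sire == "A" & labels[plan$cohort] == "A"])
  expect_equal(a_within, a_cows, tolerance = 1e-6)
})

test_that("rotation alternates sire breed against the last sire used", {
  cfg <- default_parameters("rot_FJ")
  cows <- rbind(
    cow_cohorts(age = 4, count = 100, comp = c(1, 0, 0), last_sire = "F"),
    cow_cohorts(age = 4, count = 100, comp = c(2 / 3, 1 / 3, 0),
                last_sire = "J"),
    cow_cohorts(age = 4, count = 100, comp = c(0.25, 0.75, 0),
                last_sire = "none") # foundation: minority breed starts
  )
  cfg$demography$straightbred_floor <- 0
  cap <- c(F = 1e9, J = 1e9, A = 1e9)
  plan <- allocate_matings(cows, "rot_FJ", cap, "F", cfg)
  ab <- plan[plan$sire != "natural", ]
  sire_of <- function(i) unique(ab$sire[ab$cohort == i])
  expect_equal(sire_of(1), "J")
  expect_equal(sire_of(2), "F")
  expect_equal(sire_of(3), "F") # minority fraction is F
})
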