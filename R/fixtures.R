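# Fixture generation: scaled base populations, synthetic "actuals" CSVs with
# known injected trends, and randomized small instances for property tests.
# Fixtures are the only place randomness enters; the simulator itself is
# deterministic.

#' Fixture specification
#'
#' @param seed Integer seed for the fixture's pseudo-random source.
#' @param scale Total cow count (default 10,000 for fast tests; use 3.2e6 for
#'   full-scale runs).
#' @param trend Injected per-trait phenotypic trend (units/yr) for the
#'   synthetic actuals series.
#' @param noise_sd Per-trait noise SD around the linear actuals series.
#' @param years Year range of the actuals series.
#' @return List of class `herdsim_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, scale = 10000,
                         trend = c(milk = 45.6, fat = 2.67, protein = 2.30,
                                   liveweight = -0.39),
                         noise_sd = c(milk = 0, fat = 0, protein = 0,
                                      liveweight = 0),
                         years = 1996:2018) {
  stopifnot(scale > 0, all(noise_sd >= 0))
  spec <- list(seed = as.integer(seed), scale = scale,
               trend = as_trait_vector(trend),
               noise_sd = as_trait_vector(noise_sd), years = years)
  class(spec) <- "herdsim_fixture_spec"
  spec
}

#' Build a scaled base population
#'
#' A start-year state honoring all parameter invariants, with total cows equal
#' to `spec$scale` exactly. Deterministic given the seed: the seed perturbs
#' cohort merits slightly (SD 0.02 genetic SD) so that selection is
#' non-trivial even in small test populations.
#'
#' @param spec A [fixture_spec()].
#' @param config Optional base configuration (default [default_parameters()]).
#' @return A `herdsim_state`.
#' @export
make_base_population <- function(spec, config = default_parameters()) {
  config$init$total_cows <- spec$scale
  state <- initialize_base_population(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  sds <- sqrt(diag(config$genetics$G))
  n <- nrow(state$cows)
  for (j in seq_along(trait_names())) {
    tr <- trait_names()[j]
    state$cows[[tr]] <- state$cows[[tr]] + stats::rnorm(n, 0, 0.02 * sds[j])
  }
  state
}

# internal: save/restore the RNG state so fixtures do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic national-statistics ("actuals") table
#'
#' Linear per-trait series with the injected slopes plus optional Gaussian
#' noise, in the actuals CSV schema (`year`, `milk_L`, `fat_kg`,
#' `protein_kg`, `bw_kg`, plus linearly interpolated label shares). With zero
#' noise, [fit_trend()] recovers the injected slopes exactly.
#'
#' @param spec A [fixture_spec()].
#' @param path Optional path; when given the table is also written as CSV.
#' @return Data frame (invisibly also written to `path` when supplied).
#' @export
make_actuals_csv <- function(spec, path = NULL) {
  years <- spec$years
  t0 <- years - years[1]
  base <- c(milk = 3700, fat = 170, protein = 130, liveweight = 450)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  noise <- function(tr) stats::rnorm(length(years), 0, spec$noise_sd[[tr]])
  shares0 <- c(F = 0.60, J = 0.24, FxJ = 0.13, A = 0.03)
  shares1 <- c(F = 0.36, J = 0.09, FxJ = 0.53, A = 0.01)
  frac <- t0 / max(t0)
  out <- data.frame(
    year = years,
    milk_L = base[["milk"]] + spec$trend[["milk"]] * t0 + noise("milk"),
    fat_kg = base[["fat"]] + spec$trend[["fat"]] * t0 + noise("fat"),
    protein_kg = base[["protein"]] + spec$trend[["protein"]] * t0 +
      noise("protein"),
    bw_kg = base[["liveweight"]] + spec$trend[["liveweight"]] * t0 +
      noise("liveweight"),
    share_F = shares0[["F"]] + frac * (shares1[["F"]] - shares0[["F"]]),
    share_J = shares0[["J"]] + frac * (shares1[["J"]] - shares0[["J"]]),
    share_FxJ = shares0[["FxJ"]] + frac * (shares1[["FxJ"]] - shares0[["FxJ"]]),
    share_A = shares0[["A"]] + frac * (shares1[["A"]] - shares0[["A"]])
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
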