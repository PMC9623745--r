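# Trend estimation and predicted-versus-actual comparison tables.

#' Fit an annual trend by ordinary least squares
#'
#' Slope and intercept of value on year. Invariant to re-centering of the
#' year axis (the slope is unchanged when all years are shifted).
#'
#' @param years Numeric vector of years (at least 3 distinct values).
#' @param values Numeric vector of the same length.
#' @return Object of class `herdsim_trend`: list with `slope` (units/yr),
#'   `intercept`, `residual_sd`, `years` (range), `n`.
#' @export
fit_trend <- function(years, values) {
  ok <- is.finite(years) & is.finite(values)
  years <- years[ok]; values <- values[ok]
  if (length(years) < 3) stop("trend estimation needs at least 3 points")
  if (stats::sd(years) == 0) stop("zero variance in years")
  fit <- stats::lm(values ~ years)
  est <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    # direct residual SD; summary.lm warns on exact fits
    residual_sd = sqrt(sum(stats::residuals(fit)^2) /
                         max(fit$df.residual, 1)),
    years = range(years),
    n = length(years)
  )
  class(est) <- "herdsim_trend"
  est
}

#' @export
print.herdsim_trend <- function(x, ...) {
  cat(sprintf("trend %.4g per year (%d-%d, n=%d, residual SD %.3g)\n",
              x$slope, x$years[1], x$years[2], x$n, x$residual_sd))
  invisible(x)
}

# internal: column names of the actuals CSV schema per trait
actual_columns <- function() {
  c(milk = "milk_L", fat = "fat_kg", protein = "protein_kg",
    liveweight = "bw_kg")
}

#' Build a predicted-versus-actual trend comparison table
#'
#' One row per trait with three trend columns: the actual phenotypic trend
#' (from the supplied national-statistics CSV), the model-predicted genetic
#' trend (from simulated annual genetic means), and the actual trend in
#' proven-sire EBVs (from optional `sire_*` columns of the CSV, NA when
#' absent). Actual columns are fitted from the CSV as given, never re-derived
#' from raw industry data. Years outside the overlap of the two sources are
#' dropped listwise.
#'
#' @param predicted Annual summary data frame from [run_simulation()].
#' @param actual Data frame (or CSV path) with columns `year`, `milk_L`,
#'   `fat_kg`, `protein_kg`, `bw_kg` and optionally `sire_milk_L`,
#'   `sire_fat_kg`, `sire_protein_kg`, `sire_bw_kg`.
#' @param years Optional year window (length-2 vector) over which to fit.
#' @return Data frame with columns `trait`, `actual_phenotypic`,
#'   `predicted_genetic`, `actual_sire`.
#' @export
build_comparison <- function(predicted, actual, years = NULL) {
  if (is.character(actual)) actual <- utils::read.csv(actual)
  need <- c("year", unname(actual_columns()))
  miss <- setdiff(need, names(actual))
  if (length(miss))
    stop("actuals data missing columns: ", paste(miss, collapse = ", "))
  overlap <- intersect(predicted$year, actual$year)
  if (!is.null(years))
    overlap <- overlap[overlap >= years[1] & overlap <= years[2]]
  if (length(overlap) < 3)
    stop("fewer than 3 overlapping years between predicted and actual series")
  p <- predicted[predicted$year %in% overlap, , drop = FALSE]
  a <- actual[actual$year %in% overlap, , drop = FALSE]
  cols <- actual_columns()
  rows <- lapply(trait_names(), function(tr) {
    sire_col <- paste0("sire_", cols[[tr]])
    data.frame(
      trait = tr,
      actual_phenotypic = fit_trend(a$year, a[[cols[[tr]]]])$slope,
      predicted_genetic = fit_trend(p$year, p[[tr]])$slope,
      actual_sire = if (sire_col %in% names(a))
        fit_trend(a$year, a[[sire_col]])$slope else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write the annual summary of a run to CSV
#'
#' @param result A `herdsim_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annual_summary <- function(result, path) {
  utils::write.csv(result$summary, path, row.names = FALSE)
  invisible(path)
}

#' Plot breed-composition or genetic-trend trajectories
#'
#' Base-graphics line charts of the simulated label shares (`what =
#' "composition"`) or per-trait genetic means (`what = "trends"`).
#'
#' @param x A `herdsim_result`.
#' @param what `"composition"` or `"trends"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.herdsim_result <- function(x, what = c("composition", "trends"), ...) {
  what <- match.arg(what)
  s <- x$summary
  if (what == "composition") {
    cols <- paste0("share_", c("F", "J", "A", "FxJ"))
    graphics::matplot(s$year, 100 * as.matrix(s[, cols]), type = "l", lty = 1,
                      xlab = "Year", ylab = "Share of national herd (%)", ...)
    graphics::legend("topright", legend = c("F", "J", "A", "FxJ"),
                     col = seq_len(4), lty = 1, bty = "n")
  } else {
    graphics::matplot(s$year, scale(as.matrix(s[, trait_names()]),
                                    center = TRUE, scale = FALSE),
                      type = "l", lty = 1, xlab = "Year",
                      ylab = "Genetic mean (deviation from 1996)", ...)
    graphics::legend("topleft", legend = trait_names(), col = seq_len(4),
                     lty = 1, bty = "n")
  }
  invisible(x)
}
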