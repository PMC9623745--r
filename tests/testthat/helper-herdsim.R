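# Shared helpers: small configurations and brute-force oracles.

# a fast configuration: full parameter set, short horizon
small_config <- function(strategy = "best_bulls", end_year = 2004, ...) {
  cfg <- default_parameters(strategy)
  cfg$end_year <- end_year
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  validate_config(cfg)
  cfg
}

# Monte-Carlo oracle for truncation across age classes: simulate candidates,
# rank on estimated merit, cut at the common threshold.
mc_truncation_oracle <- function(pools, n_required, n_draws = 1e6, seed = 42) {
  set.seed(seed)
  total <- sum(pools$count)
  n_k <- round(n_draws * pools$count / total)
  merit <- unlist(lapply(seq_len(nrow(pools)), function(k) {
    stats::rnorm(n_k[k], pools$mean[k], pools$sd[k])
  }))
  class_id <- rep(seq_len(nrow(pools)), n_k)
  keep <- round(n_draws * n_required / total)
  sel <- class_id[order(merit, decreasing = TRUE)[seq_len(keep)]]
  counts <- tabulate(sel, nbins = nrow(pools))
  counts * total / n_draws
}

# random valid breed composition
random_comp <- function() {
  x <- stats::runif(3)
  x / sum(x)
}
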