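test_that("breeding worth is the exact inner product with economic values", {
  v <- default_economic_values()
  expect_equal(breeding_worth(c(0, 1, 0, 0), v), 0.47)
  expect_equal(breeding_worth(c(0, 0, 1, 0), v), 4.054)
  expect_equal(breeding_worth(c(1, 0, 0, 0), v), -0.05)
  expect_equal(breeding_worth(c(0, 0, 0, 1), v), -0.427)
  expect_equal(breeding_worth(c(0, 0, 0, 0), v), 0)
  # hand dot product: 100*(-0.05) + 5*0.47 + 4*4.054 + 10*(-0.427)
  expect_equal(breeding_worth(c(100, 5, 4, 10), v), 9.296)
})

test_that("breeding worth is exactly linear", {
  set.seed(11)
  for (rep in 1:20) {
    x <- rnorm(4, 0, 50); y <- rnorm(4, 0, 50)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    expect_equal(breeding_worth(a * x + b * y),
                 a * breeding_worth(x) + b * breeding_worth(y))
  }
})

test_that("aggregate SD matches closed forms and rejects non-PSD input", {
  expect_equal(aggregate_sd(diag(4), c(1, 0, 0, 0)), 1)
  expect_equal(aggregate_sd(diag(c(4, 9, 0, 0)), c(1, 1, 0, 0)), sqrt(13))
  bad <- diag(4); bad[1, 1] <- -1
  expect_error(aggregate_sd(bad, rep(1, 4)), "positive semi-definite")
})

test_that("cow reliability follows the repeated-records formula", {
  expect_equal(cow_reliability(1, 0.3, 0.5), 0.3)
  expect_equal(cow_reliability(3, 0.3, 0.5), 0.45) # 0.9 / 2.0
  expect_equal(cow_reliability(0, 0.3, 0.5), 0)
  r <- vapply(1:60, cow_reliability, numeric(1), h2 = 0.3, repeatability = 0.5)
  expect_true(all(diff(r) > 0))           # strictly increasing
  expect_true(all(r < 0.3 / 0.5))         # bounded by the asymptote
  expect_equal(r[60], 0.3 / 0.5, tolerance = 0.02)
})

test_that("bull reliability follows the half-sib progeny-test formula", {
  expect_equal(bull_reliability(0, 0.3), 0)
  expect_equal(bull_reliability(74, 0.30), 74 / (74 + (4 - 0.3) / 0.3))
  expect_equal(bull_reliability(74, 0.30), 0.857, tolerance = 1e-3)
  r <- vapply(c(1, 10, 74, 300, 5000), bull_reliability, numeric(1), h2 = 0.3)
  expect_true(all(diff(r) > 0) && all(r < 1))
  expect_equal(bull_reliability(1e7, 0.3), 1, tolerance = 1e-5)
})

test_that("single-class truncation matches normal theory", {
  pools <- data.frame(count = 1000, mean = 0, sd = 1)
  out <- truncate_across_classes(pools, 100)
  expect_equal(out$threshold, qnorm(0.9), tolerance = 1e-6)
  expect_equal(out$intensity, dnorm(qnorm(0.9)) / 0.1, tolerance = 1e-6)
  expect_equal(out$intensity, 1.7550, tolerance = 1e-4)
  expect_equal(sum(out$selected), 100)
})

test_that("identical classes share selection symmetrically", {
  pools <- data.frame(count = c(500, 500), mean = c(10, 10), sd = c(4, 4))
  out <- truncate_across_classes(pools, 500)
  expect_equal(out$selected[1], out$selected[2])
  expect_equal(sum(out$selected), 500)
})

test_that("multi-class truncation agrees with a Monte-Carlo ranking oracle", {
  cases <- list(
    data.frame(count = c(4000, 2500, 1200), mean = c(30, 18, 5),
               sd = c(12, 12, 15)),
    data.frame(count = c(900, 900, 900), mean = c(0, 5, 10), sd = c(8, 6, 4)),
    data.frame(count = c(5000, 300), mean = c(0, 25), sd = c(10, 5))
  )
  for (i in seq_along(cases)) {
    pools <- cases[[i]]
    n_req <- round(0.1 * sum(pools$count))
    out <- truncate_across_classes(pools, n_req)
    oracle <- mc_truncation_oracle(pools, n_req, n_draws = 1e6, seed = 100 + i)
    expect_equal(out$selected, oracle, tolerance = 0.01 * sum(pools$count) /
                   max(out$selected))
    expect_lt(max(abs(out$selected - oracle)), 0.01 * sum(pools$count))
  }
})

test_that("truncation threshold is monotone in the number required", {
  pools <- data.frame(count = c(100, 200, 50), mean = c(5, 0, -3),
                      sd = c(2, 3, 1))
  th <- vapply(c(10, 50, 120, 300), function(n)
    truncate_across_classes(pools, n)$threshold, numeric(1))
  expect_true(all(diff(th) < 0))
  expect_error(truncate_across_classes(pools, 351), "exceeds total")
  all_sel <- truncate_across_classes(pools, 350)
  expect_equal(all_sel$selected, pools$count)
})

test_that("zero-SD classes are selected all-or-nothing with proportional ties", {
  pools <- data.frame(count = c(10, 10, 100), mean = c(5, 5, 0), sd = c(0, 0, 3))
  out <- truncate_across_classes(pools, 10)
  # threshold sits at the tied degenerate classes: they split evenly
  expect_equal(out$selected[1], out$selected[2], tolerance = 1e-6)
  expect_equal(sum(out$selected), 10, tolerance = 1e-6)
})

test_that("selection response matches the regression formula and an MC oracle", {
  g <- default_genetic_parameters()
  v <- default_economic_values()
  expect_equal(unname(selection_response(0, 0.8, g$G, v)), rep(0, 4),
               ignore_attr = TRUE)
  # single-trait limit: diagonal G, weight on protein only
  Gd <- diag(c(100, 25, 16, 9))
  r <- selection_response(1.5, 1, Gd, c(0, 0, 1, 0))
  expect_equal(unname(r), 1.5 * c(0, 0, 16, 0) / 4, ignore_attr = TRUE)
  expect_equal(attr(r, "aggregate"), 1.5 * 4)

  # stochastic oracle: select on a noisy index, measure realized superiority
  set.seed(7)
  rel <- 0.857; p <- 0.1; n <- 1e5
  L <- chol(g$G)
  gmat <- matrix(rnorm(n * 4), n, 4) %*% L
  Tvals <- as.numeric(gmat %*% v)
  sigma_T <- aggregate_sd(g$G, v)
  ebv <- rel * Tvals + rnorm(n, 0, sqrt(rel * (1 - rel)) * sigma_T)
  sel <- ebv >= quantile(ebv, 1 - p)
  i_p <- dnorm(qnorm(1 - p)) / p
  pred <- selection_response(i_p, rel, g$G, v)
  obs <- colMeans(gmat[sel, ])
  expect_equal(unname(obs), unname(pred), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("response is linear in intensity and bounded in the aggregate", {
  g <- default_genetic_parameters()
  v <- default_economic_values()
  r1 <- selection_response(1, 0.6, g$G, v)
  r2 <- selection_response(2, 0.6, g$G, v)
  expect_equal(unname(2 * r1), unname(r2), ignore_attr = TRUE)
  sigma_T <- aggregate_sd(g$G, v)
  for (i in c(0.5, 1, 2.5)) {
    agg <- attr(selection_response(i, 0.9, g$G, v), "aggregate")
    expect_lte(agg, i * sigma_T + 1e-9)
  }
})

test_that("pathway aggregation follows the gene-flow ratio", {
  zero <- trait_vector()
  expect_equal(unname(pathway_contribution(list(zero, zero), c(5, 5))),
               rep(0, 4), ignore_attr = TRUE)
  R <- trait_vector(milk = 120, fat = 6, protein = 5, liveweight = 1)
  expect_equal(pathway_contribution(list(R), 6), R / 6)
  # four pathways with hand-set differentials: (10+6+4+0)/(7+5+6.5+4.5)
  resp <- list(10, 6, 4, 0)
  expect_equal(pathway_contribution(resp, c(7, 5, 6.5, 4.5)), 20 / 23)
})
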