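test_that("stability curves validate their points", {
  expect_error(stability_curve(c(0, 10, 5), c(1, 0.9, 0.8)), "increasing")
  expect_error(stability_curve(c(0, 10), c(1, 1.2)), "0, 1")
  expect_error(stability_curve(numeric(0), numeric(0)), "non-empty")
  cv <- stability_curve(c(0, 50), c(1, 0.8), label = "x")
  expect_equal(attr(cv, "label"), "x")
})

test_that("the SSE objective does interpolated least-squares arithmetic", {
  sim <- tibble::tibble(generation = 0:10, S = rep(1, 11))
  flat9 <- stability_curve(seq(0, 8, by = 2), rep(0.9, 5))
  expect_equal(sse_objective(sim, flat9), 5 * 0.01, tolerance = 1e-12)
  expect_equal(sse_objective(sim, stability_curve(0, 1)), 0)
  # linear interpolation between recorded generations
  sim2 <- tibble::tibble(generation = c(0, 10), S = c(1, 0))
  expect_equal(sse_objective(sim2, stability_curve(5, 0.5)), 0, tolerance = 1e-12)
  expect_error(sse_objective(sim, stability_curve(c(0, 20), c(1, 0.5))),
               "horizon")
})

test_that("a loss-free curve is explained by zero failures / even segregation", {
  flat <- stability_curve(seq(0, 100, by = 25), rep(1, 5))
  fa <- fit_alpha(flat, n0 = 15, grid = c(0, 0.25, 0.5), replicates = 3, seed = 1)
  expect_equal(fa$estimate, 0)
  fd <- fit_delta(flat, n0 = 15, grid = c(0.4, 0.45, 0.5), seed = 1)
  expect_equal(fd$estimate, 0.5)
  expect_equal(split_ratio(fd$estimate), "50:50")
})

test_that("fits are deterministic in the seed and invariant to grid order", {
  curve <- gen_stability_dataset(alpha = 0.8, n0 = 15,
                                 generations = seq(0, 80, 20), seed = 4,
                                 replicates = 5)
  g <- seq(0.6, 1.0, by = 0.2)
  f1 <- fit_alpha(curve, 15, grid = g, replicates = 4, seed = 9)
  f2 <- fit_alpha(curve, 15, grid = rev(g), replicates = 4, seed = 9)
  expect_equal(f1$estimate, f2$estimate)
  expect_equal(f1$objective, f2$objective)
  f3 <- fit_alpha(curve, 15, grid = g, replicates = 4, seed = 9)
  expect_equal(glance(f1), glance(f3))
})

test_that("tidy and glance expose the evaluated grid and the summary", {
  curve <- stability_curve(c(0, 40, 80), c(1, 0.9, 0.7))
  fit <- fit_delta(curve, n0 = 12, grid = c(0.40, 0.45, 0.50), seed = 2)
  td <- tidy(fit)
  expect_named(td, c("term", "value", "beta", "objective"))
  expect_equal(nrow(td), 3)
  expect_equal(unique(td$term), "delta")
  gl <- glance(fit)
  expect_equal(gl$parameter, "delta")
  expect_equal(gl$estimate, fit$estimate)
  expect_equal(min(td$objective), fit$objective)
})

test_that("local refinement narrows the grid around the minimizer", {
  curve <- gen_stability_dataset(alpha = 0, delta = 0.44, n0 = 20,
                                 generations = seq(0, 120, 20),
                                 colonies_scored = 1e6, seed = 3)
  fit <- fit_delta(curve, n0 = 20, grid = seq(0.38, 0.50, by = 0.04),
                   seed = 1, refine = 2)
  expect_lt(abs(fit$estimate - 0.44), 0.021)
  expect_gt(nrow(fit$grid), 4) # refined points were evaluated
})

test_that("a joint beta grid returns the best (value, beta) pair", {
  curve <- gen_stability_dataset(alpha = 0, delta = 0.49, beta = 0.95, n0 = 14,
                                 generations = seq(0, 100, 25),
                                 colonies_scored = 1e6, seed = 8)
  fit <- fit_delta(curve, n0 = 14, grid = c(0.47, 0.49),
                   beta_grid = c(0.90, 0.95, 1.00), seed = 1)
  expect_equal(fit$estimate, 0.49)
  expect_equal(fit$beta, 0.95)
})

test_that("replication-failure fits recover a known alpha from a clean curve", {
  curve <- gen_stability_dataset(alpha = 0.8, n0 = 20,
                                 generations = seq(0, 160, 20),
                                 colonies_scored = 1e6, replicates = 20,
                                 seed = 21)
  fit <- fit_alpha(curve, n0 = 20, grid = seq(0.5, 1.1, by = 0.1),
                   replicates = 10, seed = 2)
  expect_lt(abs(fit$estimate - 0.8) / 0.8, 0.15)
})

test_that("split ratios render partition fractions the conventional way", {
  expect_equal(split_ratio(0.40), "40:60")
  expect_equal(split_ratio(0.37), "37:63")
  expect_error(split_ratio(0.6), "delta")
})
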