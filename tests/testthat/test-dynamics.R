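test_that("failure pmf matches the closed form and normalizes", {
  expect_equal(fail_pmf(1, 1.20), exp(-1 / 1.2) - exp(-2 / 1.2), tolerance = 1e-12)
  expect_equal(round(fail_pmf(1, 1.20), 4), 0.2457)
  expect_equal(round(fail_pmf(0, 0.51), 4), 0.8593)
  expect_equal(sum(fail_pmf(0:200, 1.5)), 1, tolerance = 1e-12)
  expect_equal(fail_pmf(0:3, 0), c(1, 0, 0, 0))
  expect_error(fail_pmf(1, -0.5), "alpha")
  expect_error(fail_pmf(-1, 0.5), "non-negative")
})

test_that("failure sampler implements floor(-alpha * log(U))", {
  set.seed(42)
  draws <- sample_fail_count(1.3, 1000)
  set.seed(42)
  expect_identical(draws, floor(-1.3 * log(runif(1000))))
  expect_identical(sample_fail_count(0, 5), rep(0, 5))
})

test_that("sampler frequencies agree with the pmf", {
  set.seed(7)
  draws <- sample_fail_count(1.20, 2e5)
  expect_equal(mean(draws == 1), fail_pmf(1, 1.20), tolerance = 0.005)
  expect_equal(mean(draws == 0), fail_pmf(0, 1.20), tolerance = 0.005)
})

test_that("replication multiplier covers fixed, saturating and clamped branches", {
  expect_equal(replication_multiplier(c(0, 3, 100)), c(2, 2, 2))
  pol <- saturating_policy(a = 1, b = 0.1, n_max = 40)
  expect_equal(replication_multiplier(40, pol), 2)
  expect_lt(replication_multiplier(1e6, pol), 1.0001)
  # at the pole and beyond, the multiplier stays within [1, 1 + a]
  r <- replication_multiplier(0:80, pol)
  expect_true(all(r >= 1 & r <= 2))
})

test_that("post-replication counts subtract failures and clamp at zero", {
  expect_equal(replicate_count(2, 1), 3)
  expect_equal(replicate_count(5, 0), 10)
  expect_equal(replicate_count(1, 5), 0)
  expect_equal(replicate_count(0, 3), 0)
})

test_that("partition floors the first daughter and conserves units", {
  expect_equal(unlist(partition(3, 0.5)), c(daughter1 = 1, daughter2 = 2))
  expect_equal(unlist(partition(10, 0.40)), c(daughter1 = 4, daughter2 = 6))
  expect_equal(unlist(partition(28, 0.49)), c(daughter1 = 13, daughter2 = 15))
  set.seed(1)
  for (i in 1:20) {
    n <- sample(0:500, 1)
    dl <- runif(1, 0.01, 0.5)
    p <- partition(n, dl)
    expect_equal(p$daughter1 + p$daughter2, n)
    expect_lte(p$daughter1, p$daughter2)
  }
  expect_error(partition(4, 0), "delta")
  expect_error(partition(4, 0.6), "delta")
})

test_that("post-segregational killing floors the zero class in census mode", {
  d <- cn_distribution(c(0, 5), c(10, 4), mode = "census")
  out <- apply_psk(d, 0.8)
  expect_equal(as.data.frame(out), data.frame(n = c(0, 5), abundance = c(8, 4)),
               ignore_attr = TRUE)
  d2 <- cn_distribution(0, 5, mode = "census")
  expect_equal(apply_psk(d2, 0.5)$abundance, 2)
  expect_equal(as.data.frame(apply_psk(d, 1)), as.data.frame(d))
})

test_that("killing renormalizes in weights mode", {
  d <- cn_distribution(c(0, 4), c(0.5, 0.5))
  out <- apply_psk(d, 0.5)
  expect_equal(sum(out$abundance), 1, tolerance = 1e-12)
  expect_equal(out$abundance[out$n == 0], 1 / 3, tolerance = 1e-12)
})

test_that("one generation on the three-cell census reproduces the worked example", {
  out <- step_generation(census3(), sim_params(generations = 1),
                         fail_draws = c("2" = 1))
  expect_equal(as.data.frame(out),
               data.frame(n = c(0, 1, 2), abundance = c(2, 3, 1)),
               ignore_attr = TRUE)
})

test_that("even doubling with no failures is a fixed point of the class structure", {
  d <- cn_distribution(4, 8, mode = "census")
  out <- step_generation(d, sim_params(alpha = 0, delta = 0.5, generations = 1))
  expect_equal(as.data.frame(out), data.frame(n = 4, abundance = 16),
               ignore_attr = TRUE)
})

test_that("without killing the census doubles every generation", {
  params <- sim_params(alpha = 1.1, delta = 0.4, beta = 1, generations = 1,
                       seed = 3)
  d <- init_poisson(10, mode = "census", m0 = 500)
  set.seed(11)
  out <- step_generation(d, params)
  expect_equal(sum(out$abundance), 2 * sum(d$abundance))
})

test_that("plasmid units are conserved when replication and killing are ideal", {
  # support controls off: pruning/capping are the only unit sinks
  for (dl in c(0.5, 0.42, 0.31)) {
    tr <- simulate_trajectory(init_poisson(20),
                              sim_params(alpha = 0, delta = dl, beta = 1,
                                         generations = 40, prune_eps = 0,
                                         n_cap = 1e9))
    expect_equal(tr$PCN, rep(tr$PCN[1], nrow(tr)), tolerance = 1e-12)
  }
  # at an even split the support stays compact and the defaults are exact too
  tr <- simulate_trajectory(init_poisson(20),
                            sim_params(alpha = 0, delta = 0.5, beta = 1,
                                       generations = 300))
  expect_equal(tr$PCN, rep(tr$PCN[1], nrow(tr)), tolerance = 1e-9)
})

test_that("stability is non-increasing when plasmid-free cells persist", {
  tr <- simulate_trajectory(init_poisson(12),
                            sim_params(alpha = 1.2, delta = 0.45, beta = 1,
                                       generations = 120, seed = 5))
  expect_true(all(diff(tr$S) <= 1e-12))
})

test_that("killing plasmid-free cells drives the population mean copy number up", {
  tr <- simulate_trajectory(init_poisson(14),
                            sim_params(alpha = 0, delta = 0.49, beta = 0.9,
                                       generations = 150))
  expect_true(all(diff(tr$PCN) >= -1e-9))
  expect_gt(tr$PCN[151], tr$PCN[1])
})

test_that("trajectories include the initial state and honour the horizon", {
  tr <- simulate_trajectory(init_poisson(5), sim_params(generations = 30))
  expect_equal(nrow(tr), 31)
  expect_equal(tr$generation[1], 0)
  expect_equal(tr$S[1], 1)
  expect_equal(tr$PCN[1], mean_pcn(init_poisson(5)), tolerance = 1e-9)
})

test_that("ensembles are reproducible and degenerate correctly without noise", {
  params <- sim_params(alpha = 0.9, generations = 40, replicates = 8, seed = 123)
  e1 <- simulate_ensemble(init_poisson(15), params)
  e2 <- simulate_ensemble(init_poisson(15), params)
  expect_identical(as.data.frame(e1), as.data.frame(e2))

  det <- sim_params(alpha = 0, delta = 0.45, generations = 40, replicates = 10)
  ens <- simulate_ensemble(init_poisson(15), det)
  single <- simulate_trajectory(init_poisson(15), det)
  expect_equal(ens$S, single$S, tolerance = 1e-12)
  expect_equal(ens$PCN, single$PCN, tolerance = 1e-12)
  expect_true(all(ens$S_sd == 0))
})

test_that("class pruning does not perturb the stability series", {
  run <- function(eps) {
    simulate_trajectory(init_poisson(20),
                        sim_params(alpha = 0, delta = 0.49, beta = 1,
                                   generations = 300, prune_eps = eps))$S
  }
  expect_lt(max(abs(run(1e-10) - run(1e-14))), 1e-6)
})

test_that("the copy-number cap bounds the support", {
  tr <- simulate_trajectory(init_poisson(20),
                            sim_params(alpha = 0, delta = 0.45, beta = 0.9,
                                       generations = 100, n_cap = 64),
                            keep_distributions = TRUE)
  expect_true(all(purrr::map_lgl(tr$dist, ~ max(.x$n) <= 64)))
})

test_that("parameter validation rejects out-of-range model constants", {
  expect_error(sim_params(alpha = -1), "alpha")
  expect_error(sim_params(delta = 0), "delta")
  expect_error(sim_params(delta = 0.7), "delta")
  expect_error(sim_params(beta = 1.4), "beta")
})
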