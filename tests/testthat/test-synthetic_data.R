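test_that("expected count tables are the model's deterministic twin", {
  cnt <- expected_counts(0.0014, 0.0036, 200, 0.0071, totals = 1e6,
                         dmax = 500)
  expect_equal(cnt$n0 + cnt$n1 + cnt$n2, cnt$total, tolerance = 1e-12)
  # far rows approach the single-site independence products
  far <- expected_counts(1, 0, 100, 0.0071,
                         totals = tibble::tibble(distance = 1e7, total = 1))
  expect_equal(far$n2, (0.0071 / 1.0071)^2, tolerance = 1e-6)
  expect_equal(far$n0, (1 / 1.0071)^2, tolerance = 1e-6)
  # gamma = 0 collapses onto the crossover-only table at the same kappa
  a <- expected_counts(0.002, 0, 123, 0.0071, totals = 1e5, dmax = 50)
  b <- expected_counts(0.002, 0, 7, 0.0071, totals = 1e5, dmax = 50)
  expect_equal(a$n2, b$n2, tolerance = 1e-14)
})

test_that("multinomial sampling is seeded, exact and mean-unbiased", {
  expect_tbl <- expected_counts(0.002, 0.004, 100, 0.0071, totals = 1e4,
                                dmax = 5)
  s1 <- sample_counts(expect_tbl, seed = 11)
  s2 <- sample_counts(expect_tbl, seed = 11)
  expect_identical(s1, s2)
  s3 <- sample_counts(expect_tbl, seed = 12)
  expect_false(identical(s1, s3))
  expect_true(all(s1$n0 + s1$n1 + s1$n2 == s1$total))

  # zero-total rows stay zero
  z <- expect_tbl
  z$total[2] <- 0; z$n0[2] <- 0; z$n1[2] <- 0; z$n2[2] <- 0
  sz <- sample_counts(z, seed = 5)
  expect_equal(unlist(sz[2, c("n0", "n1", "n2")]), c(n0 = 0, n1 = 0, n2 = 0))

  # CLT: the mean over many draws matches the expectation within 3 SE
  one <- expect_tbl[3, ]
  draws <- purrr::map_dfr(1:1000, function(s) sample_counts(one, seed = s))
  for (col in c("n0", "n1", "n2")) {
    p <- one[[col]] / one$total
    se <- sqrt(one$total * p * (1 - p)) / sqrt(1000)
    expect_lt(abs(mean(draws[[col]]) - one[[col]]), 3 * se + 1e-9)
  }

  # seed handling is local: the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(sample_counts(expect_tbl, seed = 3))
  expect_identical(runif(1), before)
})

test_that("coalescent simulation reproduces the single-site expectation", {
  skip_if_not(has_coalescent_engine(), "msprime not importable")
  sim <- simulate_genomes(theta = 0.0071, kappa = 0.0014, gamma = 0.0036,
                          tract_mean = 200, sequence_length = 1e6,
                          n_individuals = 4, seed = 31)
  h <- marginal_het(sim$hets, sim$intervals, n_individuals = 4)
  # genealogies are shared across individuals, so allow generous MC slack
  expect_equal(h, 0.0071 / 1.0071, tolerance = 0.25)
  expect_true(all(sim$hets$position >= 0 & sim$hets$position < 1e6))
  expect_equal(attr(sim, "seed"), 31)
  expect_match(attr(sim, "engine"), "msprime")

  # identical seeds give identical data
  sim2 <- simulate_genomes(theta = 0.0071, kappa = 0.0014, gamma = 0.0036,
                           tract_mean = 200, sequence_length = 1e6,
                           n_individuals = 4, seed = 31)
  expect_identical(sim$hets, sim2$hets)
})

test_that("no recombination shows maximal zygosity correlation", {
  skip_if_not(has_coalescent_engine(), "msprime not importable")
  # The correlation is an ensemble property over genealogies: one
  # non-recombining simulation is a single tree, under which sites are
  # independent Poisson mutations. Pool independent blocks to realise the
  # ensemble, then the pooled data must look completely linked.
  sims <- purrr::map(1:20, function(s) {
    simulate_genomes(theta = 0.0071, kappa = 0, gamma = 0, tract_mean = 100,
                     sequence_length = 3e4, n_individuals = 1,
                     seed = 9000 + s)
  })
  counts <- purrr::map(sims, function(sim) {
    count_pairs(sim$hets, sim$intervals, dmax = 200)
  })
  cnt <- pool_counts(dplyr::bind_rows(counts))
  n_hets <- sum(purrr::map_int(sims, ~ nrow(.x$hets)))
  h <- n_hets / (20 * 3e4)
  # H2 excess over the independence product: complete linkage doubles it
  p2_obs <- sum(cnt$n2) / sum(cnt$total)
  expect_gt(p2_obs / h^2, 1.2)
  # collapsed-trinomial rho estimate sits near the complete-linkage end
  collapsed <- tibble::tibble(
    chromosome = "pool", distance = 1L,
    n0 = sum(cnt$n0), n1 = sum(cnt$n1), n2 = sum(cnt$n2),
    total = sum(cnt$total)
  )
  prof <- fit_rho_profile(collapsed, theta = theta_from_het(h),
                          dmin = 1, dmax = 1)
  expect_lt(prof$rho_hat, 10)
})

test_that("parametric bootstrap summarises estimator spread", {
  expect_error(
    parametric_bootstrap(0.0071, 0.002, 0.004, 100, n_replicates = 0),
    "n_replicates"
  )
  boot <- parametric_bootstrap(
    theta = 0.0071, kappa = 0.002, gamma = 0.004, tract_mean = 120,
    n_replicates = 8, mode = "multinomial", sequence_length = 1e6,
    n_individuals = 10, seed = 3
  )
  expect_equal(nrow(boot) + attr(boot, "n_failed"), 8L)
  qs <- attr(boot, "quantiles")
  expect_setequal(qs$term, c("kappa", "gamma", "tract_mean"))
  # interval from multinomial noise at large totals covers the truth
  expect_lte(qs$q025[qs$term == "kappa"], 0.002)
  expect_gte(qs$q975[qs$term == "kappa"], 0.002)
  expect_lte(qs$q025[qs$term == "gamma"], 0.004)
  expect_gte(qs$q975[qs$term == "gamma"], 0.004)
  # reproducible given the master seed
  boot2 <- parametric_bootstrap(
    theta = 0.0071, kappa = 0.002, gamma = 0.004, tract_mean = 120,
    n_replicates = 8, mode = "multinomial", sequence_length = 1e6,
    n_individuals = 10, seed = 3
  )
  expect_equal(boot$kappa, boot2$kappa)
})
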