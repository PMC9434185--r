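th19 <- chr19_truth$theta

test_that("single-distance log-likelihood follows the trinomial form", {
  zero <- tibble::tibble(n0 = 0, n1 = 0, n2 = 0)
  expect_identical(loglik_at_distance(zero, 0.0071, 3), 0)

  # counts proportional to the model probabilities are maximised at the
  # generating rho (grid-search oracle)
  p <- two_locus_probs(th19, 25)
  cnt <- tibble::tibble(n0 = 1e6 * p$p0, n1 = 1e6 * p$p1, n2 = 1e6 * p$p2)
  grid <- seq(0, 1000, by = 0.5)
  ll <- vapply(grid, function(r) loglik_at_distance(cnt, th19, r), 0)
  expect_equal(grid[which.max(ll)], 25, tolerance = 0.5 / 25)

  # linkage inflates both H0 and H2, so all-H0 (and all-H2) data are
  # maximised at the rho = 0 boundary, while H1-only data favour free
  # recombination
  all0 <- tibble::tibble(n0 = 1e5, n1 = 0, n2 = 0)
  ll <- vapply(grid, function(r) loglik_at_distance(all0, th19, r), 0)
  expect_equal(which.max(ll), 1L)
  all2 <- tibble::tibble(n0 = 0, n1 = 0, n2 = 1e5)
  ll <- vapply(grid, function(r) loglik_at_distance(all2, th19, r), 0)
  expect_equal(which.max(ll), 1L)
  all1 <- tibble::tibble(n0 = 0, n1 = 1e5, n2 = 0)
  ll <- vapply(grid, function(r) loglik_at_distance(all1, th19, r), 0)
  expect_equal(which.max(ll), length(grid))
})

test_that("rho profile reproduces the generating curve on expected counts", {
  cnt <- expected_counts(chr19_truth$kappa, chr19_truth$gamma,
                         chr19_truth$tract_mean, th19, totals = 1e6,
                         dmax = 300)
  prof <- fit_rho_profile(cnt, th19, dmin = 1, dmax = 300)
  want <- rho_total(prof$distance, chr19_truth$kappa, chr19_truth$gamma,
                    chr19_truth$tract_mean)
  expect_equal(prof$rho_hat, want, tolerance = 1e-6)
  # conversion bends the per-bp profile downward in d
  expect_true(all(diff(prof$rho_per_bp) < 0))

  # crossover only: flat per-bp profile at kappa
  co <- expected_counts(0.003, 0, 100, th19, totals = 1e6, dmax = 100)
  prof <- fit_rho_profile(co, th19, dmin = 1, dmax = 100)
  expect_equal(prof$rho_per_bp, rep(0.003, 100), tolerance = 1e-6)
})

test_that("composite likelihood sums per-distance terms and peaks at truth", {
  cnt <- expected_counts(0.002, 0.004, 100, th19, totals = 1e5, dmax = 400)
  one <- cnt[cnt$distance == 137, ]
  expect_equal(
    composite_loglik(cnt, 0.002, 0.004, 100, th19, dmin = 137, dmax = 137),
    loglik_at_distance(one, th19, rho_total(137, 0.002, 0.004, 100))
  )
  # coarse 11^3 grid bracketing the truth has its argmax at the truth
  ks <- 0.002 * seq(0.5, 1.5, length.out = 11)
  gs <- 0.004 * seq(0.5, 1.5, length.out = 11)
  Ls <- 100 * seq(0.5, 1.5, length.out = 11)
  best <- c(NA, NA, NA); best_ll <- -Inf
  for (k in ks) for (g in gs) for (L in Ls) {
    v <- composite_loglik(cnt, k, g, L, th19, dmin = 1, dmax = 400)
    if (v > best_ll) { best_ll <- v; best <- c(k, g, L) }
  }
  expect_equal(best, c(0.002, 0.004, 100), tolerance = 1e-9)
  expect_error(composite_loglik(cnt, 1, 1, 1, th19, dmin = 10, dmax = 5),
               "dmin")
})

test_that("chromosome fit recovers generating parameters from clean data", {
  cnt <- expected_counts(chr19_truth$kappa, chr19_truth$gamma,
                         chr19_truth$tract_mean, th19, totals = 1e5)
  fit <- fit_chromosome(cnt, th19, dmin = 100, dmax = 1000)
  est <- fit$estimates
  expect_equal(est$kappa, chr19_truth$kappa, tolerance = 5e-3)
  expect_equal(est$gamma, chr19_truth$gamma, tolerance = 5e-3)
  expect_equal(est$tract_mean, chr19_truth$tract_mean, tolerance = 5e-3)
  expect_true(fit$convergence == 0)

  # the fit's maximum dominates the truth's own likelihood
  at_truth <- composite_loglik(cnt, chr19_truth$kappa, chr19_truth$gamma,
                               chr19_truth$tract_mean, th19)
  expect_gte(fit$loglik + 1e-8, at_truth)

  # broom-style accessors
  td <- tidy(fit)
  expect_setequal(td$term, c("kappa", "gamma", "tract_mean"))
  gl <- glance(fit)
  expect_equal(gl$n_param, 3L)
  expect_equal(gl$logLik, fit$loglik)
})

test_that("nested crossover-only truth is recovered and never outfits the full model", {
  cnt <- expected_counts(0.0025, 0, 100, th19, totals = 1e6)
  fit <- fit_chromosome(cnt, th19, dmin = 100, dmax = 1000)
  expect_lte(fit$estimates$gamma, 1e-6)
  expect_equal(fit$estimates$kappa, 0.0025, tolerance = 1e-3)
  # CO-only profile likelihood (1-D oracle over kappa, gamma = 0)
  co_ll <- stats::optimize(
    function(k) composite_loglik(cnt, k, 0, 100, th19),
    c(1e-6, 0.1), maximum = TRUE, tol = 1e-12
  )$objective
  expect_gte(fit$loglik + 1e-6, co_ll)
})

test_that("fit with fixed tract mean estimates only the two rates", {
  cnt <- expected_counts(0.0012, 0.0006, 108, 0.0038, totals = 2e5)
  fit <- fit_chromosome(cnt, 0.0038, fix_tract_mean = 108)
  expect_equal(fit$estimates$tract_mean, 108)
  expect_equal(fit$estimates$kappa, 0.0012, tolerance = 2e-3)
  expect_equal(fit$estimates$gamma, 0.0006, tolerance = 2e-3)
  expect_equal(glance(fit)$n_param, 2L)
})

test_that("estimates from noisy counts spread around the truth", {
  expect_fit <- expected_counts(0.002, 0.004, 120, th19, totals = 2e5)
  ests <- purrr::map_dfr(1:20, function(s) {
    noisy <- sample_counts(expect_fit, seed = 1000 + s)
    f <- fit_chromosome(noisy, th19, n_starts = 2, seed = s)
    f$estimates
  })
  # empirical 95% interval of each parameter covers its truth
  expect_lte(quantile(ests$kappa, 0.025), 0.002)
  expect_gte(quantile(ests$kappa, 0.975), 0.002)
  expect_lte(quantile(ests$gamma, 0.025), 0.004)
  expect_gte(quantile(ests$gamma, 0.975), 0.004)
  expect_lte(quantile(ests$tract_mean, 0.025), 120)
  expect_gte(quantile(ests$tract_mean, 0.975), 120)
  # and the centre is close
  expect_equal(median(ests$kappa), 0.002, tolerance = 0.1)
  expect_equal(median(ests$gamma), 0.004, tolerance = 0.25)
})

test_that("joint shared-L fit decouples chromosomes and averages L", {
  # K = 1 reduces to the single-chromosome fit
  cnt <- expected_counts(0.002, 0.004, 100, th19, totals = 1e5)
  single <- fit_chromosome(cnt, th19)
  joint <- fit_joint_shared_L(cnt, th19)
  expect_equal(joint$estimates$kappa, single$estimates$kappa,
               tolerance = 1e-3)
  expect_equal(joint$estimates$tract_mean, single$estimates$tract_mean,
               tolerance = 1e-2)

  # three chromosomes, distinct rates, one L
  kap <- c(0.0015, 0.002, 0.0026); gam <- c(0.0022, 0.0035, 0.0046)
  cnts <- purrr::map_dfr(1:3, function(i) {
    expected_counts(kap[i], gam[i], 108, th19, totals = 1e5,
                    chromosome = paste0("chr", i))
  })
  fit <- fit_joint_shared_L(cnts, th19)
  expect_equal(fit$estimates$tract_mean, rep(108, 3), tolerance = 0.01)
  expect_equal(fit$estimates$kappa, kap, tolerance = 0.01)
  expect_equal(fit$estimates$gamma, gam, tolerance = 0.01)
  expect_equal(glance(fit)$n_param, 2L * 3L + 1L)

  # mismatched generating L: the shared estimate lies between them
  mm <- dplyr::bind_rows(
    expected_counts(0.002, 0.004, 60, th19, totals = 1e5, chromosome = "a"),
    expected_counts(0.002, 0.004, 200, th19, totals = 1e5, chromosome = "b")
  )
  fit <- fit_joint_shared_L(mm, th19)
  L <- fit$estimates$tract_mean[1]
  expect_gt(L, 60); expect_lt(L, 200)
})

test_that("likelihood surface peaks at the fit and shows negative ridges", {
  cnt <- expected_counts(chr19_truth$kappa, chr19_truth$gamma,
                         chr19_truth$tract_mean, th19, totals = 1e5)
  fit <- fit_chromosome(cnt, th19)
  for (vars in list(c("kappa", "tract_mean"), c("gamma", "tract_mean"))) {
    surf <- cl_surface(cnt, th19, fit, vars = vars, n = 15, span = 3)
    expect_lte(max(surf$loglik), fit$loglik + 1e-6)
    # grid argmax sits at the grid point nearest the MCL estimate
    top <- surf[which.max(surf$loglik), ]
    for (v in vars) {
      expect_equal(log10(top[[v]]), log10(fit$estimates[[v]]),
                   tolerance = 0.2)
    }
    # ridge: conditional argmax of the second axis falls as the first rises
    ridge <- surf |>
      dplyr::group_by(.data[[vars[1]]]) |>
      dplyr::slice_max(.data$loglik, n = 1) |>
      dplyr::ungroup()
    expect_lt(stats::cor(log10(ridge[[vars[1]]]), log10(ridge[[vars[2]]])), 0)
  }
})
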