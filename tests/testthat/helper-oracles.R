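# Independent oracles used across the test files. These are deliberately
# naive (enumeration, grid search, re-typed formulas) and must stay
# independent of the package's implementation paths.

# Exhaustive O(len * dmax) pair enumeration: walk every in-interval pair
# {p, p + d} and classify it by het membership.
enum_count_pairs <- function(pos, intervals, dmax) {
  hs <- as.integer(pos)
  out <- data.frame(distance = seq_len(dmax), n0 = 0L, n1 = 0L, n2 = 0L,
                    total = 0L)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    for (d in seq_len(dmax)) {
      if (e - s - d <= 0) next
      p1 <- s:(e - 1 - d)
      k <- (p1 %in% hs) + ((p1 + d) %in% hs)
      out$total[d] <- out$total[d] + length(p1)
      out$n0[d] <- out$n0[d] + sum(k == 0L)
      out$n1[d] <- out$n1[d] + sum(k == 1L)
      out$n2[d] <- out$n2[d] + sum(k == 2L)
    }
  }
  out
}

# Independent re-typing of the zygosity-correlation rational function,
# assembled Horner-style in rho (different evaluation order from the
# package source).
delta_oracle <- function(theta, rho) {
  num <- theta * ((18 + 18 * theta + 4 * theta^2) + rho * (1 + theta))
  den <- (18 + 54 * theta + 40 * theta^2 + 8 * theta^3) +
    rho * (13 + 19 * theta + 6 * theta^2) +
    rho^2 * (1 + theta)
  num / den
}

# Grid-search maximiser of a single-distance trinomial log-likelihood.
grid_argmax_rho <- function(n0, n1, n2, theta, rho_grid) {
  ll <- vapply(rho_grid, function(r) {
    p <- as.numeric(two_locus_probs(theta, r)[, c("p0", "p1", "p2")])
    sum(c(n0, n1, n2) * ifelse(p > 0, log(p), -Inf), na.rm = FALSE)
  }, 0)
  rho_grid[which.max(ll)]
}

# Shared small generating truths.
chr19_truth <- list(kappa = 0.00267, gamma = 0.0044, tract_mean = 113.24,
                    theta = 0.0071)
fig1_truth <- list(kappa = 0.0014, gamma = 0.0036, tract_mean = 200,
                   theta = 0.0071)
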