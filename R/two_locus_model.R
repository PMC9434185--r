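#' Zygosity correlation between two sites
#'
#' The deviation of the joint two-locus zygosity-state probabilities from
#' their independence products, for a neutral Wright--Fisher population with
#' population-scaled mutation rate `theta` (per site) and total
#' population-scaled recombination rate `rho` between the two sites. The
#' correlation is a rational function of `theta` and `rho`; it equals
#' `theta / (1 + 2 * theta)` at `rho = 0` (complete linkage) and decays to 0
#' as `rho` grows (free recombination).
#'
#' The function is evaluated exactly as the closed form is written, in double
#' precision, with no algebraic rearrangement: the regime of use
#' (`theta < 0.1`, `rho < 1e4`) is numerically benign and this keeps results
#' bit-reproducible.
#'
#' @param theta Population-scaled mutation rate per site (4N mu), >= 0.
#' @param rho Population-scaled total recombination rate between the two
#'   sites, >= 0. Recycled against `theta`.
#' @return Numeric vector of correlations, each in `[0, theta/(1+2*theta)]`.
#' @examples
#' zygosity_correlation(0.0071, 0)        # theta / (1 + 2 theta)
#' zygosity_correlation(0.0071, c(0, 1, 10, 100))
#' @export
zygosity_correlation <- function(theta, rho) {
  check_theta_rho(theta, rho)
  num <- theta * (18 + rho + 18 * theta + rho * theta + 4 * theta^2)
  den <- 18 + 13 * rho + rho^2 + 54 * theta + 40 * theta^2 + 8 * theta^3 +
    rho * (rho * theta + 19 * theta + 6 * theta^2)
  num / den
}

#' Expected two-locus zygosity-state probabilities
#'
#' For one diploid individual and a pair of sites, the three zygosity states
#' are H0 (neither site heterozygous), H1 (exactly one) and H2 (both). Their
#' expectations under the neutral model are
#' `p0 = (1 + Delta * theta) / (1 + theta)^2`,
#' `p2 = (theta^2 + Delta * theta) / (1 + theta)^2` and
#' `p1 = 1 - p0 - p2`, where `Delta` is [zygosity_correlation()]. Tight
#' linkage (small `rho`) inflates H0 and H2 at the expense of H1.
#'
#' `theta = 0` returns exactly `(1, 0, 0)` by a guarded branch.
#'
#' @inheritParams zygosity_correlation
#' @return A tibble with columns `theta`, `rho`, `p0`, `p1`, `p2`; rows sum
#'   to 1.
#' @examples
#' two_locus_probs(0.0071, c(0, 10, 1e6))
#' @export
two_locus_probs <- function(theta, rho) {
  p <- state_prob_matrix(theta, rho)
  n <- nrow(p)
  tibble::tibble(
    theta = rep_len(theta, n), rho = rep_len(rho, n),
    p0 = as.numeric(p[, 1L]), p1 = as.numeric(p[, 2L]),
    p2 = as.numeric(p[, 3L])
  )
}

# Internal: n x 3 matrix of (p0, p1, p2); the hot path for the likelihood.
state_prob_matrix <- function(theta, rho) {
  check_theta_rho(theta, rho)
  n <- max(length(theta), length(rho))
  theta <- rep_len(theta, n)
  rho <- rep_len(rho, n)
  delta <- ifelse(theta == 0, 0, zygosity_correlation(theta, rho))
  denom <- (1 + theta)^2
  p0 <- (1 + delta * theta) / denom
  p2 <- (theta^2 + delta * theta) / denom
  p1 <- 1 - p0 - p2
  out <- cbind(unname(p0), unname(p1), unname(p2))
  colnames(out) <- c("p0", "p1", "p2")
  zero <- theta == 0
  if (any(zero)) out[zero, ] <- rep(c(1, 0, 0), each = sum(zero))
  out
}

#' Total recombination rate between two sites at distance d
#'
#' Decomposes the total population-scaled recombination rate between two
#' sites `d` base pairs apart into crossover and gene-conversion components:
#' `rho(d) = kappa * d + 2 * gamma * L * (1 - exp(-d / L))`, where `kappa`
#' is the per-bp crossover rate (4Nc), `gamma` the per-bp gene-conversion
#' initiation rate (4Ng) and `L = tract_mean` the mean of the exponential
#' tract-length distribution in bp. A conversion tract separates the two
#' sites only if it covers exactly one of them, which is what makes the
#' gene-conversion term saturate at `2 * gamma * L` for `d >> L` while the
#' per-bp rate `rho(d)/d` decays from `kappa + 2 * gamma` (d -> 0, large L)
#' to `kappa`.
#'
#' `(1 - exp(-d/L))` is evaluated via [expm1()] so short distances
#' (`d << L`), which carry the gene-conversion signal, do not lose precision.
#'
#' @param d Distance(s) between the sites in base pairs, non-negative.
#' @param kappa Per-bp population-scaled crossover rate, >= 0.
#' @param gamma Per-bp population-scaled gene-conversion initiation rate,
#'   >= 0.
#' @param tract_mean Mean gene-conversion tract length in bp, > 0.
#' @return Numeric vector of total rates, same length as `d`.
#' @examples
#' rho_total(1:10, kappa = 0.00267, gamma = 0.0044, tract_mean = 113.24)
#' @export
rho_total <- function(d, kappa, gamma, tract_mean) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("`d` must be finite and non-negative", call. = FALSE)
  }
  check_recomb_params(kappa, gamma, tract_mean)
  kappa * d + 2 * gamma * tract_mean * (-expm1(-d / tract_mean))
}

#' Plug-in theta from observed heterozygosity
#'
#' Inverts the single-site expectation `E[H] = theta / (1 + theta)`:
#' given an observed heterozygous fraction `h`, returns
#' `theta = h / (1 - h)`.
#'
#' @param h Observed fraction of heterozygous sites, in `[0, 1)`.
#' @return Estimate of theta (4N mu per site).
#' @examples
#' theta_from_het(0.00705)
#' @export
theta_from_het <- function(h) {
  if (any(!is.finite(h)) || any(h < 0) || any(h >= 1)) {
    stop("`h` must lie in [0, 1)", call. = FALSE)
  }
  h / (1 - h)
}

check_theta_rho <- function(theta, rho) {
  if (any(!is.finite(theta)) || any(theta < 0)) {
    stop("`theta` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(rho)) || any(rho < 0)) {
    stop("`rho` must be finite and >= 0", call. = FALSE)
  }
  invisible(NULL)
}

check_recomb_params <- function(kappa, gamma, tract_mean) {
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    stop("`kappa` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(gamma)) || any(gamma < 0)) {
    stop("`gamma` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(tract_mean)) || any(tract_mean <= 0)) {
    stop("`tract_mean` must be finite and > 0", call. = FALSE)
  }
  invisible(NULL)
}
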