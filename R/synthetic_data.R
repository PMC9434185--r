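#' Noise-free expected count table under a recombination model
#'
#' The deterministic twin of the model: for each distance `d`, the row is
#' `total_d * (p0, p1, p2)` evaluated at `rho = rho_total(d, kappa, gamma,
#' tract_mean)`. Counts are fractional; rows sum to `total_d` exactly. Used
#' for self-consistency tests (fitting such a table must recover the
#' generating parameters) and as the probability source for multinomial
#' sampling.
#'
#' @inheritParams rho_total
#' @param theta Population-scaled mutation rate per site.
#' @param totals Either a tibble with columns `distance`, `total` (and
#'   optionally `chromosome`) or a single number used for every distance in
#'   `1..dmax`.
#' @param dmax Largest distance when `totals` is scalar. Default 1000.
#' @param chromosome Chromosome label when `totals` is scalar. Default
#'   `"sim"`.
#' @return A fractional count table: `chromosome`, `distance`, `n0`, `n1`,
#'   `n2`, `total`.
#' @examples
#' expected_counts(kappa = 0.0014, gamma = 0.0036, tract_mean = 200,
#'                 theta = 0.0071, totals = 1e6, dmax = 10)
#' @export
expected_counts <- function(kappa, gamma, tract_mean, theta, totals,
                            dmax = 1000, chromosome = "sim") {
  if (is.numeric(totals) && length(totals) == 1L) {
    totals <- tibble::tibble(
      chromosome = chromosome, distance = seq_len(dmax), total = totals
    )
  }
  stopifnot(is.data.frame(totals),
            all(c("distance", "total") %in% names(totals)))
  if (!"chromosome" %in% names(totals)) totals$chromosome <- chromosome
  rho <- rho_total(totals$distance, kappa, gamma, tract_mean)
  p <- state_prob_matrix(theta, rho)
  tibble::tibble(
    chromosome = totals$chromosome,
    distance = totals$distance,
    n0 = totals$total * as.numeric(p[, 1L]),
    n1 = totals$total * as.numeric(p[, 2L]),
    n2 = totals$total * as.numeric(p[, 3L]),
    total = totals$total
  )
}

#' Multinomial sampling of a count table
#'
#' Replaces each row of an expected (fractional) count table with a seeded
#' trinomial draw of size `total` and probabilities proportional to
#' `(n0, n1, n2)`. Rows with `total = 0` stay zero. Reproducible given
#' `seed`; the seed handling is local and does not disturb the caller's RNG
#' state.
#'
#' @param expected Count table from [expected_counts()] (any table whose
#'   rows sum to `total` works); `total` must be integer-valued.
#' @param seed Integer seed.
#' @return Integer count table of the same shape.
#' @export
sample_counts <- function(expected, seed) {
  validate_counts(expected)
  if (any(expected$total != round(expected$total))) {
    stop("`total` must be integer-valued for sampling", call. = FALSE)
  }
  with_seed(seed, {
    draw <- function(n0, n1, n2, total) {
      if (total == 0) return(c(0, 0, 0))
      as.numeric(stats::rmultinom(1L, total, c(n0, n1, n2) / total))
    }
    m <- purrr::pmap(
      list(expected$n0, expected$n1, expected$n2, expected$total), draw
    )
    m <- do.call(rbind, m)
    out <- expected
    out$n0 <- m[, 1L]; out$n1 <- m[, 2L]; out$n2 <- m[, 3L]
    out
  })
}

#' Is the coalescent engine available?
#'
#' The coalescent mode shells out to the msprime Python library through the
#' `python` binary on the PATH. Returns `TRUE` when that import succeeds.
#'
#' @param python Python binary. Default `"python"`.
#' @return Logical.
#' @export
has_coalescent_engine <- function(python = "python") {
  if (Sys.which(python) == "") return(FALSE)
  code <- suppressWarnings(system2(
    python, c("-c", shQuote("import msprime")),
    stdout = FALSE, stderr = FALSE
  ))
  identical(code, 0L)
}

#' Simulate diploid genomes with crossover and gene conversion
#'
#' Runs a neutral constant-size coalescent (msprime, through Python) with
#' per-bp crossover rate, per-bp gene-conversion initiation rate and
#' exponential tract lengths, overlays mutations, and extracts the
#' heterozygous-site positions of each simulated diploid. Only the
#' population-scaled parameters matter; internally the engine is given a
#' reference diploid size `ne` and per-generation rates `mu = theta/(4 ne)`,
#' `c = kappa/(4 ne)`, `g = gamma/(4 ne)` (the conversion is recorded in the
#' result's attributes).
#'
#' The default mutation model is the engine's finite-sites default, under
#' which recurrent mutation at a site can mask heterozygosity and inflates
#' short-distance rho estimates slightly; `mutation_model =
#' "infinite_alleles"` gives every mutation a fresh allele for bias-free
#' estimator tests.
#'
#' @inheritParams expected_counts
#' @param sequence_length Simulated sequence length in bp.
#' @param n_individuals Number of diploid individuals. Default 10.
#' @param seed Integer seed passed to the engine.
#' @param ne Reference diploid population size for the parameter
#'   conversion. Default 1e4.
#' @param mutation_model `"finite_sites"` (engine default) or
#'   `"infinite_alleles"`.
#' @param python Python binary used to reach the engine.
#' @return A list with `hets` (tibble `individual`, `chromosome`,
#'   `position`) and `intervals` (the single simulated block); attributes
#'   record the seed, engine version and parameter conversion.
#' @export
simulate_genomes <- function(theta, kappa, gamma, tract_mean,
                             sequence_length, n_individuals = 10, seed = 1,
                             ne = 1e4, chromosome = "sim",
                             mutation_model = c("finite_sites",
                                                "infinite_alleles"),
                             python = "python") {
  mutation_model <- match.arg(mutation_model)
  check_recomb_params(kappa, gamma, tract_mean)
  if (!has_coalescent_engine(python)) {
    stop("coalescent engine not available: `", python,
         "` cannot import msprime. Install msprime or use the multinomial ",
         "mode of parametric_bootstrap().", call. = FALSE)
  }
  script <- system.file("python", "simulate_diploids.py", package = "rhogc",
                        mustWork = TRUE)
  out_tsv <- tempfile(fileext = ".tsv")
  meta_json <- tempfile(fileext = ".json")
  on.exit(unlink(c(out_tsv, meta_json)), add = TRUE)
  args <- c(
    shQuote(script),
    "--theta", theta, "--kappa", kappa, "--gamma", gamma,
    "--tract-mean", tract_mean, "--sequence-length",
    format(sequence_length, scientific = FALSE),
    "--individuals", n_individuals, "--seed", seed, "--ne",
    format(ne, scientific = FALSE),
    "--mutation-model", mutation_model,
    "--out", shQuote(out_tsv), "--meta", shQuote(meta_json)
  )
  status <- system2(python, args, stdout = "", stderr = "")
  if (!identical(status, 0L)) {
    stop("coalescent simulation failed (exit ", status, ")", call. = FALSE)
  }
  pos <- readr::read_tsv(out_tsv, col_types = readr::cols(
    individual = readr::col_integer(), position = readr::col_double()
  ))
  meta <- jsonlite::read_json(meta_json)
  hets <- tibble::tibble(
    individual = pos$individual, chromosome = chromosome,
    position = pos$position
  )
  res <- list(
    hets = hets,
    intervals = tibble::tibble(
      chromosome = chromosome, start = 0, end = sequence_length
    )
  )
  attr(res, "seed") <- seed
  attr(res, "engine") <- meta$engine
  attr(res, "conversion") <- meta$conversion
  res
}

#' Parametric bootstrap / power analysis of the estimator
#'
#' Repeats simulate -> count -> fit under known parameters and summarises
#' the spread of the estimates. Two noise modes:
#' \describe{
#'   \item{multinomial}{draws each replicate's count table trinomially from
#'     the model expectations (fast, engine-free; exercises the estimator
#'     alone). Per-distance totals default to
#'     `n_individuals * (sequence_length - d)`, one contiguous block per
#'     individual.}
#'   \item{coalescent}{simulates diploid genomes with [simulate_genomes()],
#'     counts pairs, then fits (exercises counting, the estimator, and
#'     genealogical noise).}
#' }
#' A master seed spawns per-replicate seeds deterministically; every
#' replicate's seed is reported. Replicate-level fit failures are dropped
#' with a message and counted in the output.
#'
#' @inheritParams simulate_genomes
#' @param n_replicates Number of bootstrap replicates, >= 1.
#' @param mode `"multinomial"` or `"coalescent"`.
#' @param totals Optional explicit per-distance totals (scalar or tibble)
#'   for the multinomial mode, overriding the sequence-length default.
#' @param dmin,dmax Distance range for the fits.
#' @param fix_tract_mean Optional fixed L passed to every fit.
#' @param n_starts Multi-starts per replicate fit (kept small: replicates
#'   only need to land on the global ridge, the spread dominates).
#' @param seed Master seed.
#' @return A tibble (class `rhogc_bootstrap`) with one row per successful
#'   replicate (`replicate`, `seed`, `kappa`, `gamma`, `tract_mean`,
#'   `loglik`); attributes `truth`, `n_failed`, and `quantiles` (2.5/50/
#'   97.5% per parameter).
#' @export
parametric_bootstrap <- function(theta, kappa, gamma, tract_mean,
                                 n_replicates,
                                 mode = c("multinomial", "coalescent"),
                                 sequence_length = 1e6, n_individuals = 10,
                                 totals = NULL, dmin = 100, dmax = 1000,
                                 fix_tract_mean = NULL, n_starts = 3,
                                 seed = 1, ne = 1e4, python = "python") {
  mode <- match.arg(mode)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  rep_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max - 1L, n_replicates))
  if (mode == "multinomial") {
    if (is.null(totals)) {
      totals <- tibble::tibble(
        chromosome = "sim", distance = seq_len(dmax),
        total = n_individuals * pmax(0, sequence_length - seq_len(dmax))
      )
    }
    expect <- expected_counts(kappa, gamma, tract_mean, theta, totals,
                              dmax = dmax)
  }

  one <- function(i) {
    s <- rep_seeds[[i]]
    cnt <- if (mode == "multinomial") {
      sample_counts(expect, seed = s)
    } else {
      sim <- simulate_genomes(theta, kappa, gamma, tract_mean,
                              sequence_length, n_individuals, seed = s,
                              ne = ne, python = python)
      pool_counts(count_pairs(sim$hets, sim$intervals, dmax = dmax))
    }
    fit <- fit_chromosome(cnt, theta = theta, dmin = dmin, dmax = dmax,
                          fix_tract_mean = fix_tract_mean,
                          n_starts = n_starts, seed = s)
    tibble::tibble(
      replicate = i, seed = s,
      kappa = fit$estimates$kappa, gamma = fit$estimates$gamma,
      tract_mean = fit$estimates$tract_mean, loglik = fit$loglik
    )
  }
  runs <- purrr::map(seq_len(n_replicates), function(i) {
    tryCatch(one(i), error = function(e) {
      message("replicate ", i, " failed: ", conditionMessage(e))
      NULL
    })
  })
  ok <- purrr::compact(runs)
  if (length(ok) == 0L) stop("all bootstrap replicates failed", call. = FALSE)
  out <- dplyr::bind_rows(ok)
  qs <- out |>
    tidyr::pivot_longer(c("kappa", "gamma", "tract_mean"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      q025 = stats::quantile(.data$estimate, 0.025),
      q50 = stats::quantile(.data$estimate, 0.5),
      q975 = stats::quantile(.data$estimate, 0.975),
      .groups = "drop"
    )
  attr(out, "truth") <- c(kappa = kappa, gamma = gamma,
                          tract_mean = tract_mean, theta = theta)
  attr(out, "n_failed") <- n_replicates - length(ok)
  attr(out, "quantiles") <- qs
  attr(out, "mode") <- mode
  class(out) <- c("rhogc_bootstrap", class(out))
  out
}
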