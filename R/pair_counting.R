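#' Filter and truncate analysis intervals
#'
#' Keeps intervals strictly longer than `min_len` and truncates each
#' survivor to its first `dmax` bases. With a `strand` column, "first" means
#' the 5' end (`-` strand intervals are truncated from their upper
#' coordinate); without one, the lower coordinate is used. This mirrors the
#' usual preparation of intronic intervals for two-locus counting: short
#' introns are dropped and only the start of each long intron enters the
#' analysis, so very long (selectively atypical) introns do not dominate.
#'
#' @param intervals Tibble with columns `chromosome`, `start`, `end`
#'   (0-based half-open) and optionally `strand` ("+"/"-").
#' @param min_len Minimum interval length in bp; intervals with
#'   `end - start <= min_len` are dropped (strict, so a 1001 bp interval
#'   passes the default 1000 bp filter). Default 1000.
#' @param dmax Number of leading bases retained per interval. Default 1000.
#' @return Tibble of prepared intervals, sorted by chromosome and start.
#' @examples
#' iv <- tibble::tibble(chromosome = "19", start = 0, end = 5000)
#' prepare_intervals(iv)
#' @export
prepare_intervals <- function(intervals, min_len = 1000, dmax = 1000) {
  intervals <- validate_intervals(intervals)
  kept <- dplyr::filter(intervals, .data$end - .data$start > min_len)
  if (nrow(kept) == 0L) return(kept)
  len <- pmin(kept$end - kept$start, dmax)
  if ("strand" %in% names(kept)) {
    minus <- !is.na(kept$strand) & kept$strand == "-"
    kept$start <- ifelse(minus, kept$end - len, kept$start)
    kept$end <- kept$start + len
  } else {
    kept$end <- kept$start + len
  }
  dplyr::arrange(kept, .data$chromosome, .data$start)
}

#' Number of within-interval site pairs at each distance
#'
#' For each distance `d` in `1..dmax`, the number of unordered site pairs
#' `{p, p + d}` with both positions inside one interval: an interval of
#' length `len` contributes `max(0, len - d)` pairs. Pairs never span two
#' intervals. These totals are the denominators of the per-distance
#' zygosity-state frequencies.
#'
#' @inheritParams prepare_intervals
#' @param dmax Largest distance, bp.
#' @return Tibble with columns `chromosome`, `distance`, `total`.
#' @export
pair_totals <- function(intervals, dmax = 1000) {
  intervals <- validate_intervals(intervals)
  intervals |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(
        distance = seq_len(dmax),
        total = totals_from_lengths(df$end - df$start, dmax)
      )
    }) |>
    dplyr::ungroup()
}

# sum over intervals of max(0, len - d) for every d in 1..dmax, via
# cumulative sums over the sorted lengths (avoids the intervals x dmax outer)
totals_from_lengths <- function(len, dmax) {
  len <- sort(as.numeric(len))
  cs <- c(0, cumsum(len))
  tot <- cs[length(cs)]
  d <- seq_len(dmax)
  k <- findInterval(d, len)  # number of lengths <= d (contribute nothing)
  (tot - cs[k + 1]) - d * (length(len) - k)
}

#' Two-locus zygosity-state counts per distance
#'
#' Converts the heterozygous-site positions of diploid individuals within
#' analysis intervals into per-distance counts of the three zygosity states:
#' for each distance `d` in `1..dmax`, `n2` is the number of within-interval
#' pairs `{p, p + d}` with both sites heterozygous, `n1` the number with
#' exactly one, and `n0` the remainder of the `total` available pairs. Sites
#' inside the intervals that are absent from `hets` are treated as
#' homozygous. Counts are returned per chromosome and individual; use
#' [pool_counts()] to combine individuals.
#'
#' @param hets Tibble of heterozygous-site records with columns
#'   `chromosome`, `position` (0-based) and optionally `individual`; each
#'   position must fall inside one of the prepared intervals.
#' @param intervals Prepared intervals, see [prepare_intervals()].
#' @param dmax Largest pair distance in bp. Default 1000.
#' @return Tibble with columns `individual` (if present in `hets`),
#'   `chromosome`, `distance`, `n0`, `n1`, `n2`, `total`.
#' @examples
#' iv <- tibble::tibble(chromosome = "chr1", start = 0, end = 10)
#' h <- tibble::tibble(chromosome = "chr1", position = c(2, 5))
#' count_pairs(h, iv, dmax = 3)
#' @export
count_pairs <- function(hets, intervals, dmax = 1000) {
  intervals <- validate_intervals(intervals)
  stopifnot(is.data.frame(hets), all(c("chromosome", "position") %in% names(hets)))
  has_ind <- "individual" %in% names(hets)
  groups <- if (has_ind) c("individual", "chromosome") else "chromosome"
  totals <- pair_totals(intervals, dmax)
  if (nrow(hets) == 0L) {
    # no heterozygous sites: every available pair is H0
    return(dplyr::mutate(totals, n0 = .data$total, n1 = 0L, n2 = 0L) |>
             dplyr::select("chromosome", "distance", "n0", "n1", "n2",
                           "total"))
  }

  one_group <- function(df, key) {
    chrom <- key$chromosome[[1L]]
    iv <- intervals[intervals$chromosome == chrom, ]
    count_pairs_one(sort(unique(df$position)), iv$start, iv$end, dmax)
  }
  counted <- hets |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(one_group) |>
    dplyr::ungroup() |>
    dplyr::left_join(totals, by = c("chromosome", "distance")) |>
    dplyr::mutate(n0 = .data$total - .data$n1 - .data$n2)
  if (any(counted$n0 < 0)) {
    stop("internal error: negative n0; are intervals prepared?", call. = FALSE)
  }
  dplyr::select(
    counted, dplyr::any_of("individual"), "chromosome", "distance",
    "n0", "n1", "n2", "total"
  )
}

# Core single-chromosome counter. `pos` sorted unique het positions; each
# must lie inside an interval [start, end). Returns distance, n1, n2.
count_pairs_one <- function(pos, start, end, dmax) {
  ord <- order(start)
  start <- start[ord]; end <- end[ord]
  iv_of <- findInterval(pos, start)
  inside <- iv_of >= 1L & pos < end[pmax(iv_of, 1L)]
  if (!all(inside)) {
    stop(
      "heterozygous position(s) outside the prepared intervals: ",
      paste(utils::head(pos[!inside], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  n2 <- integer(dmax)
  bb <- integer(dmax)
  for (k in seq_along(start)) {
    h <- pos[iv_of == k]
    if (length(h) == 0L) next
    # het-het pairs: differences between in-interval het positions <= dmax
    j <- findInterval(h + dmax, h)
    lens <- j - seq_along(h)
    if (any(lens > 0L)) {
      idx2 <- sequence(lens, from = seq_along(h) + 1L)
      diffs <- h[idx2] - rep.int(h, lens)
      n2 <- n2 + tabulate(diffs, nbins = dmax)
    }
    # B_d: over het positions p, [p + d in interval] + [p - d in interval];
    # counted by rank arithmetic on the sorted het vector
    d <- seq_len(dmax)
    up <- findInterval(end[k] - 1 - d, h)            # hets with p + d < end
    dn <- length(h) - findInterval(start[k] - 1 + d, h)  # hets with p - d >= start
    bb <- bb + up + dn
  }
  tibble::tibble(distance = seq_len(dmax), n1 = bb - 2L * n2, n2 = n2)
}

#' Pool count tables across individuals or replicates
#'
#' Element-wise sums of `n0`, `n1`, `n2` and `total` over tables sharing a
#' distance grid, keeping chromosomes separate. Pooling across individuals
#' treats their pair observations as exchangeable draws; the composite
#' likelihood downstream ignores the non-independence induced by shared
#' ancestry.
#'
#' @param counts A count table (or several row-bound together) as returned
#'   by [count_pairs()].
#' @return Pooled tibble with columns `chromosome`, `distance`, `n0`, `n1`,
#'   `n2`, `total`.
#' @export
pool_counts <- function(counts) {
  validate_counts(counts)
  counts |>
    dplyr::group_by(.data$chromosome, .data$distance) |>
    dplyr::summarise(
      dplyr::across(c("n0", "n1", "n2", "total"), sum),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chromosome, .data$distance)
}

#' Marginal heterozygosity over the analysis intervals
#'
#' The fraction of interval bases that are heterozygous, pooled across
#' individuals: total heterozygous positions divided by total interval
#' length times the number of individuals. Convert to a plug-in theta with
#' [theta_from_het()].
#'
#' @inheritParams count_pairs
#' @param n_individuals Number of individuals the het records cover;
#'   defaults to the number of distinct `individual` values (1 when the
#'   column is absent). Supply explicitly if some individuals carry no
#'   heterozygous site.
#' @return Heterozygous fraction in `[0, 1)`.
#' @export
marginal_het <- function(hets, intervals, n_individuals = NULL) {
  intervals <- validate_intervals(intervals)
  if (nrow(intervals) == 0L) {
    stop("empty interval set", call. = FALSE)
  }
  if (is.null(n_individuals)) {
    n_individuals <- if ("individual" %in% names(hets)) {
      dplyr::n_distinct(hets$individual)
    } else 1L
  }
  n_individuals <- max(1L, n_individuals)
  span <- sum(intervals$end - intervals$start)
  nrow(hets) / (span * n_individuals)
}

validate_intervals <- function(intervals) {
  stopifnot(is.data.frame(intervals))
  need <- c("chromosome", "start", "end")
  if (!all(need %in% names(intervals))) {
    stop("intervals need columns chromosome, start, end", call. = FALSE)
  }
  if (any(intervals$start >= intervals$end)) {
    stop("intervals must satisfy start < end (0-based half-open)", call. = FALSE)
  }
  iv <- dplyr::arrange(tibble::as_tibble(intervals), .data$chromosome, .data$start)
  overlap <- iv |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(bad = as.numeric(.data$start) <
                    dplyr::lag(cummax(as.numeric(.data$end)),
                               default = -Inf)) |>
    dplyr::pull("bad")
  if (any(overlap)) {
    stop("intervals overlap within a chromosome; merge them first ",
         "(see read_intervals)", call. = FALSE)
  }
  iv
}

validate_counts <- function(counts) {
  stopifnot(is.data.frame(counts))
  need <- c("chromosome", "distance", "n0", "n1", "n2", "total")
  if (!all(need %in% names(counts))) {
    stop("count table needs columns chromosome, distance, n0, n1, n2, total",
         call. = FALSE)
  }
  if (any(counts$n0 < 0) || any(counts$n1 < 0) || any(counts$n2 < 0)) {
    stop("negative counts", call. = FALSE)
  }
  bad <- abs(counts$n0 + counts$n1 + counts$n2 - counts$total) >
    1e-9 * pmax(1, counts$total)
  if (any(bad)) {
    stop("n0 + n1 + n2 != total at distance(s) ",
         paste(utils::head(counts$distance[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(counts)
}
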