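#' Plot a per-distance rho profile
#'
#' Per-bp recombination rate estimates against pair distance. Under
#' crossover only the profile is flat at `kappa`; gene conversion lifts it
#' towards `kappa + 2 * gamma` at short distances. Pass `expected` to
#' overlay the model curve `rho_total(d, ...) / d` as a dashed line.
#'
#' @param object A `rhogc_profile` from [fit_rho_profile()].
#' @param expected Optional named list/vector with `kappa`, `gamma`,
#'   `tract_mean` for the overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rhogc_profile <- function(object, expected = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$distance, y = .data$rho_per_bp)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = "distance between sites d (bp)",
      y = expression(hat(rho) / d ~ "per bp")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(expected)) {
    expected <- as.list(expected)
    d <- sort(unique(object$distance))
    cur <- tibble::tibble(
      distance = d,
      rho_per_bp = rho_total(d, expected$kappa, expected$gamma,
                             expected$tract_mean) / d
    )
    p <- p + ggplot2::geom_line(data = cur, linetype = "dashed",
                                colour = "firebrick")
  }
  p
}

#' Plot a composite-likelihood surface
#'
#' Filled log-likelihood surface over the two grid parameters (log axes)
#' with contours and the maximum composite-likelihood point marked.
#'
#' @param object A `rhogc_surface` from [cl_surface()].
#' @param n_contours Number of contour bins. Default 12.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rhogc_surface <- function(object, n_contours = 12, ...) {
  vars <- attr(object, "vars")
  mle <- attr(object, "mle")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[vars[1L]]], y = .data[[vars[2L]]], z = .data$loglik
  )) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$loglik)) +
    ggplot2::geom_contour(bins = n_contours, colour = "white",
                          linewidth = 0.2) +
    ggplot2::annotate("point", x = mle[[vars[1L]]], y = mle[[vars[2L]]],
                      shape = 4, size = 3, colour = "black") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "ln CL") +
    ggplot2::labs(x = vars[1L], y = vars[2L]) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap estimate spreads
#'
#' One panel per parameter: replicate estimates (points + box) with the
#' generating truth as a horizontal line.
#'
#' @param object A `rhogc_bootstrap` from [parametric_bootstrap()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rhogc_bootstrap <- function(object, ...) {
  truth <- attr(object, "truth")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), c("kappa", "gamma", "tract_mean"),
    names_to = "term", values_to = "estimate"
  )
  tr <- tibble::tibble(term = c("kappa", "gamma", "tract_mean"),
                       truth = truth[c("kappa", "gamma", "tract_mean")])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(data = tr, ggplot2::aes(yintercept = .data$truth),
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
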