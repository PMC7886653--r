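# ggplot2 displays for the main result types

#' Histogram of a variant-allele-frequency profile
#'
#' The 0.48-0.52 band used by the ploidy classifier is shaded.
#'
#' @param profile a [vaf_profile()].
#' @param bins histogram bins.
#' @param min_depth minimum total depth for a site to be shown.
#' @return A ggplot.
#' @export
plot_vaf <- function(profile, bins = 50, min_depth = 8L) {
  use <- usable_sites(profile, min_depth)
  ggplot2::ggplot(use, ggplot2::aes(x = .data$vaf)) +
    ggplot2::annotate("rect", xmin = 0.48, xmax = 0.52, ymin = -Inf, ymax = Inf,
                      alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::labs(x = "variant allele frequency", y = "sites") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ld_decay <- function(object, ...) {
  p <- ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$dist, y = .data$mean_r2)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "distance (bp)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
  if (is.finite(object$rho)) {
    dd <- seq(min(object$bins$dist), max(object$bins$dist), length.out = 200)
    fit <- tibble::tibble(dist = dd, mean_r2 = hill_weir_r2(dd, object$rho, object$n))
    p <- p + ggplot2::geom_line(data = fit, colour = "firebrick")
  }
  if (is.finite(object$extent_bp %||% NA))
    p <- p + ggplot2::geom_vline(xintercept = object$extent_bp, linetype = 2)
  p
}

#' Stacked ancestry-coefficient bar plot
#'
#' @param coeffs output of [ancestry_coefficients()].
#' @return A ggplot (samples ordered by the first proportion).
#' @export
plot_ancestry_coefficients <- function(coeffs) {
  long <- tidyr::pivot_longer(coeffs, -"sample_id",
                              names_to = "population", values_to = "proportion")
  ord <- coeffs$sample_id[order(-coeffs[[2]])]
  long$sample_id <- factor(long$sample_id, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                                     fill = .data$population)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Posterior local-ancestry track for one sample
#'
#' @param posteriors output of [hmm_posteriors()].
#' @param sites site tibble (`pos`) aligned with the posteriors.
#' @param blocks optional decoded blocks to overlay.
#' @return A ggplot.
#' @export
plot_ancestry_track <- function(posteriors, sites, blocks = NULL) {
  d <- tibble::tibble(pos = sites$pos, p_donor = posteriors$p_donor)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$p_donor)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (bp)", y = "P(donor ancestry)") +
    ggplot2::theme_minimal()
  if (!is.null(blocks) && nrow(blocks))
    p <- p + ggplot2::geom_rect(data = blocks,
                                ggplot2::aes(xmin = .data$start, xmax = .data$end),
                                ymin = -0.02, ymax = 1.02,
                                inherit.aes = FALSE, alpha = 0.15, fill = "firebrick")
  p
}

#' @export
autoplot.varcomp_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$h2), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$h2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$h2 - .data$h2_se, 0),
                                        ymax = .data$h2 + .data$h2_se), width = 0.2) +
    ggplot2::labs(x = NULL, y = expression(h^2)) +
    ggplot2::theme_minimal()
}

#' RCCR series with the detected separation segment
#'
#' @param series an [rccr_series()] in generations.
#' @param detection optional [detect_separation()] result to mark.
#' @return A ggplot (time axis log-scaled, past on the left).
#' @export
plot_rccr <- function(series, detection = NULL) {
  d <- tibble::as_tibble(series)
  d$mid <- sqrt(d$left_time_boundary * d$right_time_boundary)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$rccr)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "generations before present", y = "relative cross-coalescence rate") +
    ggplot2::theme_minimal()
  if (!is.null(detection) && nrow(detection))
    p <- p + ggplot2::geom_vline(xintercept = d$mid[detection$segment], linetype = 2,
                                 colour = "firebrick")
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
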