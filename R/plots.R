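# ggplot2 layers for the result objects

#' Volcano plot of regulation calls
#'
#' Effect estimates against -log10 adjusted p values, colored by the
#' regulation call, with the fold-change and significance thresholds drawn.
#' Following the convention of SILAC volcano plots, the x axis can be
#' flipped to control/treatment ratios with `flip_sign`.
#'
#' @param fits Tibble from [fit_ratio_model()], ideally after
#'   [call_regulated()].
#' @param fc_min,alpha Thresholds to draw; defaults 1.5 and 0.05.
#' @param flip_sign Plot control/treatment (negated) estimates.
#' @return A ggplot object, faceted by contrast.
#' @export
plot_volcano <- function(fits, fc_min = 1.5, alpha = 0.05,
                         flip_sign = FALSE) {
  if (!"regulation" %in% names(fits)) {
    fits <- call_regulated(fits, fc_min = fc_min, alpha = alpha)
  }
  d <- dplyr::filter(fits, .data$testable)
  d$x <- if (flip_sign) -d$estimate else d$estimate
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x,
                                  y = -log10(.data$p_adjust),
                                  colour = .data$regulation)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_min),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#2980b9",
                                            none = "grey70",
                                            untestable = "grey90")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast)) +
    ggplot2::labs(x = if (flip_sign) "log2 ratio (control/treatment)"
                  else "log2 ratio (treatment/control)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Bar chart of kinase-substrate enrichment scores
#'
#' @param scores Tibble from [ksea_scores()].
#' @return A ggplot object.
#' @export
plot_kinase_scores <- function(scores) {
  scores$kinase_group <- stats::reorder(scores$kinase_group, scores$score)
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$score,
                                       y = .data$kinase_group,
                                       fill = .data$score > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "#2980b9")) +
    ggplot2::labs(x = "normalized kinase score", y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.frap_fit <- function(object, ...) {
  tr <- object$trace
  tt <- seq(0, max(tr$time), length.out = 200)
  curve <- tibble::tibble(
    time = tt,
    intensity = frap_model(tt, object$f_inf, object$a_fast, object$a_slow,
                           object$k_fast, object$k_slow)
  )
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line(data = curve, colour = "#2980b9") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(attr(tr, "f_pre"), attr(tr, "f_0")),
                        linetype = "dotted", linewidth = 0.3) +
    ggplot2::labs(x = "time after bleach (s)", y = "fluorescence",
                  subtitle = sprintf("t1/2 = %.3g s, mobile = %.1f%%",
                                     object$t_half,
                                     100 * object$mobile_fraction)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.fcs_fit <- function(object, ...) {
  cv <- object$curve
  names(cv)[1:2] <- c("lag", "g")
  lag_grid <- 10^seq(log10(min(cv$lag[cv$lag > 0])), log10(max(cv$lag)),
                     length.out = 200)
  fit <- tibble::tibble(
    lag = lag_grid,
    g = fcs_model(lag_grid, object$n_particles, object$tau_d,
                  object$structure_s)
  )
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$lag, y = .data$g)) +
    ggplot2::geom_line(data = fit, colour = "#2980b9") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag (s)", y = "G(tau)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.binding_fit <- function(object, ...) {
  ti <- object$titration
  cc <- 10^seq(log10(min(ti$conc)), log10(max(ti$conc)), length.out = 200)
  fit <- tibble::tibble(conc = cc,
                        bound = competition_bound(cc, object$b0, object$kd))
  ggplot2::ggplot(ti, ggplot2::aes(x = .data$conc, y = .data$bound)) +
    ggplot2::geom_line(data = fit, colour = "#2980b9") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "competitor concentration", y = "bound fraction",
                  subtitle = sprintf("Kd = %.3g", object$kd)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.proximity_enrich <- function(object, ...) {
  p <- object$proteins
  dims <- names(p)[2:3]
  ggplot2::ggplot(p, ggplot2::aes(x = .data[[dims[1L]]],
                                  y = .data[[dims[2L]]],
                                  colour = factor(.data$cluster),
                                  shape = .data$enriched)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste("mean log10 ratio vs", dims[1L]),
                  y = paste("mean log10 ratio vs", dims[2L]),
                  colour = "group", shape = "enriched") +
    ggplot2::theme_minimal()
}
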