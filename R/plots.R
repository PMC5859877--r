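#' RF-ratio distribution of a primary screen
#'
#' Histogram of the scored clones' RF ratios with the hit cutoff (dashed) and
#' the control-derived diagnostic threshold (dotted).
#'
#' @param object a `primary_screen` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.primary_screen <- function(object, ...) {
  scored <- dplyr::filter(object$results, .data$status == "scored")
  ggplot2::ggplot(scored, ggplot2::aes(x = .data$rf_ratio)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$config$hit_cutoff,
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = object$control_threshold,
                        linetype = "dotted", colour = "blue") +
    ggplot2::labs(x = "RF ratio (mutant / control)", y = "clones",
                  title = "Primary screen RF-ratio distribution",
                  subtitle = "dashed: hit cutoff; dotted: mean + 2 SD of positive controls")
}

#' Mean RF ratio per clone in a secondary screen
#'
#' @param object a `secondary_screen` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.secondary_screen <- function(object, ...) {
  scored <- dplyr::filter(object$results, .data$status == "scored")
  ggplot2::ggplot(scored,
                  ggplot2::aes(x = .data$mean_rf_ratio,
                               fill = .data$is_final)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$config$hit_cutoff,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "forestgreen",
                                          `FALSE` = "grey35"),
                               name = "final interactor") +
    ggplot2::labs(x = "mean RF ratio over biological replicates",
                  y = "clones", title = "Secondary screen")
}

#' Per-plate control separation plot
#'
#' RF ratio of every control well by plate, coloured by control type, with
#' the hit cutoff dashed; the analogue of the global control-comparison
#' panels of a screening report.
#'
#' @param separation output of [control_separation()].
#' @param config a [screen_config()].
#' @return A ggplot.
#' @export
plot_control_separation <- function(separation, config = screen_config()) {
  ggplot2::ggplot(dplyr::filter(separation, !is.na(.data$rf_ratio)),
                  ggplot2::aes(x = .data$Plate, y = .data$rf_ratio,
                               colour = .data$WellType)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_hline(yintercept = config$hit_cutoff, linetype = "dashed") +
    ggplot2::labs(y = "RF ratio (mutant / control)",
                  title = "Control separation by plate") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Technical-replicate RF scatter plot
#'
#' @param screen_tbl canonical screen table.
#' @param strain `"control"` or `"mutant"`.
#' @param config a [screen_config()].
#' @return A ggplot of replicate 1 vs replicate 2 RF values with the Pearson
#'   r annotated.
#' @export
plot_replicate_correlation <- function(screen_tbl, strain = "control",
                                       config = screen_config()) {
  d <- add_rf_columns(dplyr::filter(screen_tbl, .data$Strain == strain),
                      config)
  rep <- replicate_correlation(d$RF_R1, d$RF_R2,
                               pair_label = paste(strain, "R1 vs R2"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$RF_R1, y = .data$RF_R2)) +
    ggplot2::geom_point(alpha = 0.4, colour = "grey25") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "RF, technical replicate 1", y = "RF, technical replicate 2",
      title = paste0(strain, " strain: r = ", round(rep$r, 2),
                     ", p ", format_p_value(rep$p_value), ", n = ", rep$n))
}
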