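# Figure-style report: readout trajectories on a shared percent-of-maximum
# axis, one trigger per panel.

#' Temporal-association plot for one trigger
#'
#' Overlays the replicate-mean trajectories of every readout of one trigger
#' on a shared percent-of-maximum axis: lines with SEM ribbons for specks
#' and cytokines, individual replicate points plus the mean for LDH — the
#' visual used to compare how closely the readouts track each other in time.
#'
#' @param panel A tidy panel containing the trigger's readouts (may include
#'   `ldh_pct`).
#' @param trigger Trigger label to plot.
#' @return A \pkg{ggplot2} object.
#' @export
plot_temporal_association <- function(panel, trigger) {
  validate_panel(panel)
  panel <- panel[panel$trigger == trigger, ]
  if (nrow(panel) == 0) stop("trigger not present in panel", call. = FALSE)
  summ <- replicate_summary(panel)
  summ <- dplyr::mutate(
    dplyr::group_by(summ, .data$readout),
    pct = percent_of_max(.data$mean),
    pct_sem = .data$sem / max(.data$mean) * 100
  )
  summ <- dplyr::ungroup(summ)
  lines <- summ[summ$readout != "ldh_pct", ]
  ldh <- summ[summ$readout == "ldh_pct", ]
  ldh_points <- aggregate_replicates(panel[panel$readout == "ldh_pct", ])

  p <- ggplot2::ggplot(lines, ggplot2::aes(x = .data$time_h, y = .data$pct,
                                           colour = .data$readout,
                                           fill = .data$readout)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pct - .data$pct_sem,
                                      ymax = .data$pct + .data$pct_sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7)
  if (nrow(ldh_points) > 0) {
    ldh_points <- dplyr::mutate(
      ldh_points, pct = .data$value / max(.data$value) * 100)
    p <- p +
      ggplot2::geom_point(data = ldh_points,
                          ggplot2::aes(x = .data$time_h, y = .data$pct),
                          colour = "red3", size = 1, alpha = 0.6,
                          inherit.aes = FALSE, show.legend = FALSE,
                          na.rm = TRUE) +
      ggplot2::geom_line(data = ldh,
                         ggplot2::aes(x = .data$time_h, y = .data$pct),
                         colour = "black", linetype = "dashed",
                         inherit.aes = FALSE)
  }
  p + ggplot2::labs(
    title = paste0("Temporal association of readouts: ", trigger),
    x = "time (h)", y = "% of maximum", colour = "readout", fill = "readout"
  ) +
    ggplot2::theme_minimal()
}
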