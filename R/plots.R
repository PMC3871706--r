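#' Plot a simulated session
#'
#' Population-mean simple-spike rate and learned eye velocity over trials,
#' with off-direction trials marked.
#'
#' @param object A `"pc_session"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pc_session <- function(object, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(c("mean_rate", "eye_velocity"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$trial, .data$value,
                                  colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "trial", y = NULL, colour = "instruction") +
    ggplot2::theme_minimal()
}

#' Plot trial-over-trial differences by pair code
#'
#' @param object A `"pc_pair_stats"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pc_pair_stats <- function(object, ...) {
  d <- filter(tidy(object), .data$n_pairs > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$code, .data$mean_d_ss)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::labs(x = "CS pair code (instruction-test)",
                  y = "trial-over-trial Δ rate (spikes/s)") +
    ggplot2::theme_minimal()
}

#' Plot the same-trial-facilitation tercile analysis
#'
#' One line of three points per cell (low/mid/high rate segment vs CS
#' probability), as in the per-neuron scatter representation.
#'
#' @param object A `"pc_terciles"`.
#' @param max_cells Cells to draw (thinned beyond this for legibility).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pc_terciles <- function(object, max_cells = 100, ...) {
  d <- tidy(object)
  cells <- unique(d$cell)
  if (length(cells) > max_cells) {
    d <- filter(d, .data$cell %in% cells[seq(1, length(cells),
                                             length.out = max_cells)])
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$mean_ss, .data$cs_prob,
                                  group = .data$cell,
                                  colour = .data$segment)) +
    ggplot2::geom_line(colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "simple-spike rate (spikes/s)",
                  y = "CS probability", colour = "segment") +
    ggplot2::theme_minimal()
}

#' Plot an ablation suite
#'
#' Per-run trial-over-trial amplitudes by variant and pair code, for firing
#' rate and behaviour.
#'
#' @param object A `"pc_ablation"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pc_ablation <- function(object, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(c("d_ss", "d_behavior"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$variant, .data$value,
                                  colour = .data$code)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6),
                        size = 0.8, alpha = 0.7, na.rm = TRUE) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "trial-over-trial Δ", colour = "pair code") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a complex-spike probability histogram
#'
#' @param data Tibble from [cs_probability_histogram()].
#' @return A ggplot object.
#' @export
plot_cs_histogram <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$bin_start + 50, .data$cs_prob)) +
    ggplot2::geom_col(width = 90, fill = "firebrick", alpha = 0.8) +
    ggplot2::labs(x = "time re instruction (ms)", y = "CS probability") +
    ggplot2::theme_minimal()
}
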