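# ggplot2 displays for the main result types. Plots are presentation only;
# no analysis step depends on them.

#' Bar plot of a peptide length distribution
#'
#' @param distribution Tibble from [length_distribution()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(distribution) {
  ggplot2::ggplot(distribution, ggplot2::aes(
    x = factor(.data$length), y = .data$count
  )) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = "peptide length (aa)", y = "peptides") +
    ggplot2::theme_minimal()
}

#' Heatmap of a motif's position frequency matrix
#'
#' @param object A [motif_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_model <- function(object, ...) {
  df <- motif_frequencies(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$position), y = .data$residue, fill = .data$frequency
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred") +
    ggplot2::labs(x = "position", y = "residue", fill = "frequency") +
    ggplot2::theme_minimal()
}

#' Fitness trace of a Gibbs clustering run
#'
#' @param object A `cluster_solution` from [gibbs_cluster()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_solution <- function(object, ...) {
  df <- tibble::tibble(
    sweep = seq_along(object$fitness_trace),
    fitness = object$fitness_trace
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$fitness)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_hline(yintercept = object$fitness, linetype = 2, color = "darkred") +
    ggplot2::labs(
      x = "sweep", y = "fitness (bits)",
      title = sprintf("k = %d, best fitness %.3f bits", object$k, object$fitness)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of expression-arm candidates: fold change vs combined rank metric
#'
#' @param scores Tibble from [select_taa_candidates()].
#' @param config The [selection_config()] used (for threshold lines).
#' @return A ggplot object.
#' @export
plot_candidates <- function(scores, config = selection_config()) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(
    x = .data$avg_fc, y = .data$rank_metric, color = .data$selected
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = config$rank_metric_min, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "darkred")) +
    ggplot2::labs(
      x = "average fold change", y = "-log10(average % rank)",
      color = "selected"
    ) +
    ggplot2::theme_minimal()
  thr <- attr(scores, "fc_threshold")
  if (!is.null(thr) && !is.na(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = 2)
  }
  p
}

#' Sensorgram with extracted phase levels
#'
#' @param sensorgram Tibble with `time_s`, `response_deg`.
#' @param phases Optional `phase_levels` from [extract_phase_levels()].
#' @return A ggplot object.
#' @export
plot_sensorgram <- function(sensorgram, phases = NULL) {
  p <- ggplot2::ggplot(sensorgram, ggplot2::aes(
    x = .data$time_s, y = .data$response_deg
  )) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::labs(x = "time (s)", y = "response (degrees)") +
    ggplot2::theme_minimal()
  if (!is.null(phases)) {
    p <- p +
      ggplot2::geom_hline(yintercept = phases$r_max, linetype = 2, color = "darkred") +
      ggplot2::geom_hline(yintercept = phases$r_min, linetype = 2, color = "steelblue")
  }
  p
}

#' Bar plot of ELISpot group means with the gate threshold
#'
#' @param gate Tibble from [elispot_gate()].
#' @return A ggplot object.
#' @export
plot_elispot <- function(gate) {
  ggplot2::ggplot(gate, ggplot2::aes(
    x = .data$group, y = .data$mean, fill = .data$selected
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      yintercept = gate$threshold[1],
      linetype = 2, color = "orange"
    ) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "darkred")) +
    ggplot2::labs(x = NULL, y = "spots per 1e6 splenocytes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
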