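#' Plot attenuated vs accelerated trajectory shares per exposure
#'
#' @param trajectory_summary Tibble from `run_study()`'s
#'   `trajectory_summary` (or a bound set of [classify_trajectories()]
#'   glances).
#' @return A ggplot.
#' @export
plot_trajectory_summary <- function(trajectory_summary) {
  long <- trajectory_summary |>
    dplyr::select("exposure", attenuated = "n_attenuated",
                  accelerated = "n_accelerated") |>
    tidyr::pivot_longer(-"exposure", names_to = "class", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$exposure, y = .data$n,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "aging-plasticity genes in signature",
                  fill = NULL,
                  title = "Exposure disruption of aging trajectories") +
    ggplot2::theme_minimal()
}

#' Autoplot a GSEA running sum
#'
#' @param object A [gsea_preranked()] result.
#' @param ... Unused.
#' @return A ggplot of the running enrichment score with the ES extremum
#'   marked.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- tibble::tibble(rank = seq_along(object$running),
                       running = object$running)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$peak, colour = "red",
                        linetype = "dotted") +
    ggplot2::labs(x = "rank", y = "running enrichment score",
                  title = paste0(object$set_name, " (ES = ",
                                 signif(object$es, 3), ")")) +
    ggplot2::theme_minimal()
}

#' Autoplot concordance categories
#'
#' @param object A [classify_concordance()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of the promoter/enhancer/both/neither
#'   partition.
#' @method autoplot concordance_result
#' @export
autoplot.concordance_result <- function(object, ...) {
  counts <- object$categories |>
    dplyr::count(.data$category, name = "n") |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = c("promoter_only", "enhancer_only",
                                               "both", "neither")))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "differential genes",
                  title = "Concordant histone-mark changes by region class") +
    ggplot2::theme_minimal()
}

#' Plot signature scores by severity state
#'
#' @param scores Score tibble from [signature_score()].
#' @param states Per-sample severity labels (parallel to the score rows).
#' @param levels Ordered severity labels.
#' @return A ggplot boxplot of scores per severity state.
#' @export
plot_severity_scores <- function(scores, states, levels) {
  df <- dplyr::mutate(scores, state = factor(states, levels = levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "disease severity", y = "summed z-score activity") +
    ggplot2::theme_minimal()
}
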