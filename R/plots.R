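#' Per-lesion class-probability profile
#'
#' Stacked-bar profile of the three class probabilities for every
#' lesion, faceted by true diagnosis — the standard way to display how
#' confidently each lesion is assigned.
#'
#' @param calls Lesion-call data frame from [run_tissue_level()] (or a
#'   `tissue_analysis`).
#' @return A ggplot object.
#' @export
plot_probability_profile <- function(calls) {
  if (inherits(calls, "tissue_analysis")) calls <- calls$calls
  long <- do.call(rbind, lapply(karyo_classes(), function(cl)
    data.frame(tissue_id = calls$tissue_id,
               true_class = calls$true_class,
               class = cl, probability = calls[[paste0("p_", cl)]],
               stringsAsFactors = FALSE)))
  long$class <- factor(long$class, levels = karyo_classes())
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$tissue_id, y = .data$probability, fill = .data$class)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::facet_grid(. ~ true_class, scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_fill_grey(start = 0.65, end = 0.2) +
    ggplot2::labs(x = "lesion", y = "class probability", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Certainty distribution by call correctness
#'
#' @param calls Lesion-call data frame (or `tissue_analysis`) with
#'   `certainty` and `correct` columns.
#' @param uncertain_below Reporting threshold drawn as a reference line
#'   (default 0.55).
#' @return A ggplot object.
#' @export
plot_certainty <- function(calls, uncertain_below = 0.55) {
  if (inherits(calls, "tissue_analysis")) calls <- calls$calls
  df <- data.frame(
    outcome = ifelse(calls$correct, "correct", "misclassified"),
    certainty = calls$certainty)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$certainty)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = uncertain_below, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "certainty (max - min probability)") +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curves
#'
#' @param roc A `roc_analysis` object.
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  stopifnot(inherits(roc, "roc_analysis"))
  long <- do.call(rbind, lapply(names(roc$curves), function(cl)
    cbind(roc$curves[[cl]], class = cl)))
  ggplot2::ggplot(long, ggplot2::aes(
    x = 1 - .data$specificity, y = .data$sensitivity,
    color = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("macro one-vs-rest AUC %.3f",
                                  roc$macro_auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
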