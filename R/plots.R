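#' Score density plot for one GO accession of a Tanimoto result
#'
#' Positive and negative Tanimoto score distributions, the visual companion
#' of the three-way separation taxonomy.
#'
#' @param object A `tanimoto_result`.
#' @param go_accession Accession to plot; defaults to the first.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tanimoto_result
#' @export
autoplot.tanimoto_result <- function(object, go_accession = NULL, ...) {
  acc <- if (is.null(go_accession)) object$summary$go_accession[1]
         else go_accession
  dat <- object$scores |>
    dplyr::filter(.data$go_accession == acc) |>
    dplyr::mutate(class = ifelse(.data$label, "positive", "negative"))
  info <- object$summary[object$summary$go_accession == acc, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_density(alpha = 0.5, adjust = 1.5) +
    ggplot2::scale_fill_manual(values = c(positive = "#3366cc",
                                          negative = "#cc3333")) +
    ggplot2::labs(
      title = sprintf("%s (%d positives): %s", acc,
                      info$n_positive, info$separation_class),
      x = "Tanimoto coefficient", y = "density", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Out-of-fold score distributions of a cross-validated model
#'
#' @param object A `go_model_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot go_model_result
#' @export
autoplot.go_model_result <- function(object, ...) {
  dat <- object$scores |>
    dplyr::mutate(class = ifelse(.data$label, "positive", "negative"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_density(alpha = 0.5, adjust = 1.5) +
    ggplot2::geom_vline(xintercept = object$metrics$threshold,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(positive = "#3366cc",
                                          negative = "#cc3333")) +
    ggplot2::labs(
      title = sprintf("%s: AUC %.3f", object$model_kind, object$metrics$auc),
      x = "out-of-fold score", y = "density", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' True rates and AUC against positive sample fraction
#'
#' Per-GO TPR, TNR and AUC plotted against each accession's positive sample
#' fraction, the standard view of how class imbalance drives model quality.
#'
#' @param object A `go_model_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot go_model_set
#' @export
autoplot.go_model_set <- function(object, ...) {
  dat <- object$metrics |>
    dplyr::select("go_accession", "positive_fraction", "tpr", "tnr", "auc") |>
    tidyr::pivot_longer(c("tpr", "tnr", "auc"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$positive_fraction,
                                    y = .data$value,
                                    color = .data$metric)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      title = sprintf("%s models, %d GO accessions", object$model_kind,
                      nrow(object$metrics)),
      x = "positive sample fraction", y = NULL, color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of unknown-strain GO matching
#'
#' Gene x GO grid of averaged scores with matched cells outlined.
#'
#' @param object A `prediction_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prediction_matrix
#' @export
autoplot.prediction_matrix <- function(object, ...) {
  dat <- object$table
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$go_accession,
                                    y = .data$gene_id,
                                    fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dat[dat$match, , drop = FALSE],
                       color = "black", linewidth = 0.6, fill = NA) +
    ggplot2::scale_fill_gradient2(low = "#cc3333", mid = "white",
                                  high = "#3366cc", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("%s score", object$model_kind)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
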