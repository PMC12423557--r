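#' Tidy a cross-validated per-GO model
#'
#' One row per training vector: its fold, out-of-fold score, true label and
#' hard prediction.
#'
#' @param x A `go_model_result` from [crossvalidate()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy go_model_result
#' @export
tidy.go_model_result <- function(x, ...) x$scores

#' One-row summary of a cross-validated per-GO model
#'
#' @param x A `go_model_result`.
#' @param ... Unused.
#' @return One-row tibble with the model kind, class counts and
#'   TPR/TNR/FPR/FNR/AUC.
#' @method glance go_model_result
#' @export
glance.go_model_result <- function(x, ...) x$metrics

#' Tidy a multi-GO model set
#'
#' @param x A `go_model_set` from [fit_go_models()].
#' @param ... Unused.
#' @return Per-GO metrics tibble (one row per accession).
#' @method tidy go_model_set
#' @export
tidy.go_model_set <- function(x, ...) x$metrics

#' One-row summary of a multi-GO model set
#'
#' @param x A `go_model_set`.
#' @param ... Passed to [summarize_metrics()].
#' @return One-row tibble of unweighted mean TPR/TNR/AUC.
#' @method glance go_model_set
#' @export
glance.go_model_set <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(model_kind = x$model_kind),
                   summarize_metrics(x$metrics, ...)$overall)
}

#' Tidy a Tanimoto model result
#'
#' @param x A `tanimoto_result` from [tanimoto_model()].
#' @param ... Unused.
#' @return Long tibble of per-vector, per-GO Tanimoto scores with labels.
#' @method tidy tanimoto_result
#' @export
tidy.tanimoto_result <- function(x, ...) x$scores

#' One-row summary of a Tanimoto model result
#'
#' @param x A `tanimoto_result`.
#' @param ... Unused.
#' @return One-row tibble with the accession count and the three
#'   separation-class counts (which partition it).
#' @method glance tanimoto_result
#' @export
glance.tanimoto_result <- function(x, ...) {
  counts <- table(factor(x$summary$separation_class,
                         levels = c("indistinguishable", "partial",
                                    "separated95")))
  tibble::tibble(
    n_go = nrow(x$summary),
    n_indistinguishable = as.integer(counts["indistinguishable"]),
    n_partial = as.integer(counts["partial"]),
    n_separated95 = as.integer(counts["separated95"])
  )
}

#' Tidy a ward clustering
#'
#' @param x A `ward_clustering`.
#' @param ... Unused.
#' @return Tibble of cluster assignments.
#' @method tidy ward_clustering
#' @export
tidy.ward_clustering <- function(x, ...) x$assignments

#' Tidy a prediction matrix
#'
#' @param x A `prediction_matrix` from [predict_unknown()].
#' @param ... Unused.
#' @return Long tibble of gene x GO scores and match flags.
#' @method tidy prediction_matrix
#' @export
tidy.prediction_matrix <- function(x, ...) x$table
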