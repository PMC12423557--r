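stratified_folds <- function(y, k) {
  y <- as.logical(y)
  folds <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# fold assignment at the group (strain) level: all vectors of a group share
# a fold, groups stratified by their class
stratified_group_folds <- function(y, groups, k) {
  y <- as.logical(y)
  groups <- as.character(groups)
  g_label <- tapply(y, groups, any)
  g_folds <- integer(length(g_label))
  names(g_folds) <- names(g_label)
  for (cls in c(TRUE, FALSE)) {
    g <- sample(names(g_label)[g_label == cls])
    g_folds[g] <- rep_len(seq_len(k), length(g))
  }
  unname(g_folds[groups])
}

#' Stratified cross-validation of one per-GO model
#'
#' Splits the real vectors into `k_folds` stratified folds; within each fold
#' the training part is SMOTE-balanced (synthetic samples never touch the
#' test fold), a model of the requested kind is fitted, and the held-out
#' vectors receive their single out-of-fold score. All fitted per-fold
#' models are retained for later unknown-strain prediction.
#'
#' Model kinds: `"rf"` (random-subspace forest, label = vote fraction > 0.5),
#' `"svm"` (RBF margin score, label = score > 0), `"tanimoto"` (score against
#' the training positives' centroid, threshold at the midpoint of the
#' training class medians).
#'
#' @param x 0/1 feature matrix of real vectors.
#' @param y Logical labels.
#' @param model `"rf"`, `"svm"` or `"tanimoto"`.
#' @param k_folds Number of folds (default 10).
#' @param balance_cfg A [balance_config()].
#' @param rf_cfg An [rf_config()] (for `model = "rf"`).
#' @param svm_cfg An [svm_config()] (for `model = "svm"`).
#' @param tune How to select SVM hyperparameters: `"once"` (one inner grid
#'   search on the full data before the outer loop, reused across folds;
#'   default) or `"per_fold"`.
#' @param seed RNG seed covering fold shuffling, balancing and model
#'   randomness.
#' @param min_positive Error floor on positives (default 10, one per fold).
#' @param groups Optional vector (e.g. gene ids) marking technical
#'   replicates: vectors sharing a group are always assigned to the same
#'   fold, so a model is never tested on the near-identical twin of a
#'   training spectrum. `NULL` gives plain vector-level stratification.
#' @return A `go_model_result`: list with `scores` (tibble: index, fold,
#'   label, score, prediction), `models` (length `k_folds`), `model_kind`,
#'   `hyper`, and `metrics` (one-row tibble via [glance()]).
#' @export
crossvalidate <- function(x, y, model = c("rf", "svm", "tanimoto"),
                          k_folds = 10, balance_cfg = balance_config(),
                          rf_cfg = rf_config(), svm_cfg = svm_config(),
                          tune = c("once", "per_fold"), seed = 1L,
                          min_positive = 10, groups = NULL) {
  model <- match.arg(model)
  tune <- match.arg(tune)
  x <- as.matrix(x)
  y <- as.logical(y)
  stopifnot(nrow(x) == length(y))
  if (sum(y) < max(k_folds, min_positive)) {
    stop("need at least ", max(k_folds, min_positive),
         " positive vectors for stratified ", k_folds, "-fold CV",
         call. = FALSE)
  }
  set.seed(seed)
  folds <- if (is.null(groups)) stratified_folds(y, k_folds)
           else stratified_group_folds(y, groups, k_folds)
  hyper <- NULL
  if (model == "svm" && tune == "once") {
    hyper <- tune_svm(x, y, svm_cfg, balance_cfg)
  }
  scores <- rep(NA_real_, length(y))
  models <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    bal <- balance(x[tr & y, , drop = FALSE], x[tr & !y, , drop = FALSE],
                   balance_cfg)
    xb <- rbind(bal$positives, bal$negatives)
    yb <- rep(c(TRUE, FALSE), c(nrow(bal$positives), nrow(bal$negatives)))
    fitted <- switch(
      model,
      rf = train_rf(xb, yb, rf_cfg),
      svm = {
        h <- if (tune == "per_fold") {
          tune_svm(x[tr, , drop = FALSE], y[tr], svm_cfg, balance_cfg)
        } else hyper
        train_svm(xb, yb, h$gamma, h$cost)
      },
      tanimoto = {
        cen <- colMeans(x[tr & y, , drop = FALSE])
        structure(list(centroid = cen), class = "tanimoto_centroid")
      }
    )
    models[[f]] <- fitted
    if (any(!tr)) {
      scores[!tr] <- predict(fitted, x[!tr, , drop = FALSE])
    }
  }
  threshold <- switch(model, rf = 0.5, svm = 0,
                      tanimoto = {
                        stats::median(c(stats::median(scores[y]),
                                        stats::median(scores[!y])))
                      })
  preds <- scores > threshold
  rates <- confusion_rates(y, preds)
  metrics <- dplyr::bind_cols(
    tibble::tibble(model_kind = model, n_positive = sum(y),
                   n_vectors = length(y),
                   positive_fraction = mean(y)),
    rates[, c("tpr", "tnr", "fpr", "fnr")],
    tibble::tibble(auc = auc(y, scores), threshold = threshold)
  )
  structure(
    list(scores = tibble::tibble(index = seq_along(y), fold = folds,
                                 label = y, score = scores,
                                 prediction = preds),
         models = models, model_kind = model, hyper = hyper,
         metrics = metrics, seed = seed, k_folds = k_folds),
    class = "go_model_result"
  )
}

#' @export
predict.tanimoto_centroid <- function(object, newdata, ...) {
  apply(as.matrix(newdata), 1L, tanimoto, b = object$centroid)
}

#' @export
print.go_model_result <- function(x, ...) {
  cat(sprintf(
    "<go_model_result> %s, %d-fold CV: AUC %.3f, TPR %.3f, TNR %.3f (%d/%d positive)\n",
    x$model_kind, x$k_folds, x$metrics$auc, x$metrics$tpr, x$metrics$tnr,
    x$metrics$n_positive, x$metrics$n_vectors
  ))
  invisible(x)
}

#' Fit cross-validated models for every eligible GO accession
#'
#' Applies [crossvalidate()] per GO accession whose positive vector count
#' reaches `min_positive` (default 20, the overfitting floor for the
#' ensemble and SVM models). Unknown-gene vectors are excluded from both
#' classes.
#'
#' @param fp A [fingerprint_set()].
#' @param go A [go_table()].
#' @param model `"rf"`, `"svm"` or `"tanimoto"`.
#' @param min_positive Eligibility floor on positive vectors.
#' @param unknown_genes Genes excluded from training.
#' @param seed Base seed; accession `i` consumes `seed + i`.
#' @inheritParams crossvalidate
#' @return A `go_model_set`: list with `results` (named list of
#'   `go_model_result`), `metrics` (per-GO tibble), `labels`, and the
#'   configs used.
#' @export
fit_go_models <- function(fp, go, model = c("rf", "svm", "tanimoto"),
                          min_positive = 20, unknown_genes = character(0),
                          k_folds = 10, balance_cfg = balance_config(),
                          rf_cfg = rf_config(), svm_cfg = svm_config(),
                          tune = c("once", "per_fold"), seed = 1L) {
  model <- match.arg(model)
  tune <- match.arg(tune)
  labels <- label_vectors(go, fp, unknown_genes)
  eligible <- labels[labels$n_positive >= min_positive, ]
  if (nrow(eligible) == 0L) {
    stop("no GO accession reaches the ", min_positive, "-positive floor",
         call. = FALSE)
  }
  results <- vector("list", nrow(eligible))
  names(results) <- eligible$go_accession
  for (i in seq_len(nrow(eligible))) {
    mask <- eligible$positive[[i]]
    use <- which(!is.na(mask))
    results[[i]] <- crossvalidate(
      fp$bits[use, , drop = FALSE], mask[use], model, k_folds, balance_cfg,
      rf_cfg, svm_cfg, tune, seed = seed + i,
      groups = fp$meta$gene_id[use]
    )
    results[[i]]$row_indices <- use
  }
  metrics <- dplyr::bind_cols(
    tibble::tibble(go_accession = eligible$go_accession),
    dplyr::bind_rows(lapply(results, function(r) r$metrics))
  )
  structure(
    list(results = results, metrics = metrics, labels = eligible,
         model_kind = model, min_positive = min_positive,
         unknown_genes = unknown_genes, seed = seed),
    class = "go_model_set"
  )
}

#' @export
print.go_model_set <- function(x, ...) {
  cat(sprintf(
    "<go_model_set> %s models for %d GO accessions (floor %d): mean AUC %.3f\n",
    x$model_kind, nrow(x$metrics), x$min_positive, mean(x$metrics$auc)
  ))
  invisible(x)
}
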