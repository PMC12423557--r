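#' Soft-margin RBF SVM settings
#'
#' Hyperparameters gamma (kernel width) and C (soft-margin penalty) are
#' selected by an inner stratified cross-validated grid search maximizing
#' AUC. The default grids are the classical coarse powers-of-four grids.
#'
#' @param gamma_grid Candidate gamma values (> 0).
#' @param c_grid Candidate C values (> 0).
#' @param inner_folds Folds of the inner selection CV (default 3).
#' @param seed Optional RNG seed for the inner fold shuffle.
#' @return An `svm_config` list.
#' @export
svm_config <- function(gamma_grid = 2^seq(-15, 3, by = 2),
                       c_grid = 2^seq(-5, 15, by = 2),
                       inner_folds = 3, seed = NULL) {
  stopifnot(length(gamma_grid) > 0, all(gamma_grid > 0),
            length(c_grid) > 0, all(c_grid > 0), inner_folds >= 2)
  structure(
    list(gamma_grid = gamma_grid, c_grid = c_grid,
         inner_folds = as.integer(inner_folds), seed = seed),
    class = "svm_config"
  )
}

fit_svm_raw <- function(x, y, gamma, cost) {
  e1071::svm(x, factor(y, levels = c(FALSE, TRUE)), kernel = "radial",
             gamma = gamma, cost = cost, scale = FALSE, probability = FALSE,
             fitted = FALSE)
}

svm_decision <- function(fit, newdata) {
  dv <- attr(predict(fit, newdata, decision.values = TRUE), "decision.values")
  out <- dv[, 1]
  # orient so that the positive (TRUE) class has positive decision values
  if (colnames(dv)[1] == "FALSE/TRUE") out <- -out
  unname(out)
}

#' Grid-search hyperparameters for the RBF SVM
#'
#' Stratified inner cross-validation on the *unbalanced* training data:
#' within each inner fold the training part is balanced (see [balance()]),
#' the held-out part is scored as-is, and the (gamma, C) pair maximizing the
#' mean inner AUC is returned. Grid points for which every inner fit is
#' degenerate are dropped; an all-degenerate grid is an error.
#'
#' @param x Feature matrix.
#' @param y Logical labels.
#' @param cfg An [svm_config()].
#' @param balance_cfg A [balance_config()] applied inside inner folds.
#' @return List with `gamma`, `cost`, and the full search `grid` tibble.
#' @export
tune_svm <- function(x, y, cfg = svm_config(),
                     balance_cfg = balance_config()) {
  x <- as.matrix(x)
  y <- as.logical(y)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  folds <- stratified_folds(y, cfg$inner_folds)
  grid <- expand.grid(gamma = cfg$gamma_grid, cost = cfg$c_grid)
  grid$auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    aucs <- rep(NA_real_, cfg$inner_folds)
    for (f in seq_len(cfg$inner_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
      bal <- balance(x[tr & y, , drop = FALSE], x[tr & !y, , drop = FALSE],
                     balance_cfg)
      fit <- tryCatch(
        fit_svm_raw(rbind(bal$positives, bal$negatives),
                    rep(c(TRUE, FALSE), c(nrow(bal$positives),
                                          nrow(bal$negatives))),
                    grid$gamma[g], grid$cost[g]),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      sc <- svm_decision(fit, x[!tr, , drop = FALSE])
      aucs[f] <- auc(y[!tr], sc)
    }
    grid$auc[g] <- mean(aucs, na.rm = TRUE)
  }
  if (all(is.nan(grid$auc) | is.na(grid$auc))) {
    stop("SVM grid search failed for every (gamma, C) point; grid: gamma in {",
         paste(signif(cfg$gamma_grid, 3), collapse = ", "), "}, C in {",
         paste(signif(cfg$c_grid, 3), collapse = ", "), "}", call. = FALSE)
  }
  best <- which.max(grid$auc)
  list(gamma = grid$gamma[best], cost = grid$cost[best],
       grid = tibble::as_tibble(grid))
}

#' Train a soft-margin RBF SVM on a balanced set
#'
#' Scores are signed decision values in margin-distance units (the decision
#' function is +/-1 on the margins), oriented so positives score above 0;
#' the hard label is score > 0.
#'
#' @param x Feature matrix (balanced training set).
#' @param y Logical labels.
#' @param gamma,cost RBF kernel width and soft-margin penalty (e.g. from
#'   [tune_svm()]).
#' @return A `margin_svm`: list with the e1071 fit and the hyperparameters.
#' @export
train_svm <- function(x, y, gamma, cost) {
  x <- as.matrix(x)
  y <- as.logical(y)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to train an SVM", call. = FALSE)
  }
  structure(list(fit = fit_svm_raw(x, y, gamma, cost),
                 gamma = gamma, cost = cost),
            class = "margin_svm")
}

#' @export
predict.margin_svm <- function(object, newdata, ...) {
  svm_decision(object$fit, as.matrix(newdata))
}

#' @export
print.margin_svm <- function(x, ...) {
  cat(sprintf("<margin_svm> RBF, gamma = %.4g, C = %.4g, %d support vectors\n",
              x$gamma, x$cost, x$fit$tot.nSV))
  invisible(x)
}
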