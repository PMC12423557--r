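#' Random-subspace forest settings
#'
#' Each tree is grown on the full training sample restricted to a small
#' random subset of fingerprint dimensions (a fresh draw without replacement
#' per tree), then the forest predicts by majority vote. This per-tree
#' feature subsetting differs from the per-split `mtry` of classical random
#' forests; the latter is available via `per_split = TRUE`.
#'
#' @param n_trees Number of trees (default 500).
#' @param features_per_tree Dimensions per tree (default 8).
#' @param per_split If `TRUE`, grow classical trees drawing candidate
#'   features at each split instead (via rpart's default behavior on all
#'   features — provided for comparison, not the protocol default).
#' @param seed Optional RNG seed consumed at training.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 500, features_per_tree = 8,
                      per_split = FALSE, seed = NULL) {
  stopifnot(n_trees >= 1, features_per_tree >= 1)
  structure(
    list(n_trees = as.integer(n_trees),
         features_per_tree = as.integer(features_per_tree),
         per_split = isTRUE(per_split), seed = seed),
    class = "rf_config"
  )
}

#' Train a random-subspace forest
#'
#' Trees are CART trees (Gini impurity) grown to purity (`cp = 0`,
#' `minsplit = 2`) on their random feature subset. Degenerate subsets with no
#' informative split yield majority-class stumps, which are valid weak
#' learners. The per-tree feature draws are retained for introspection.
#'
#' @param x 0/1 feature matrix.
#' @param y Logical class labels (both classes required).
#' @param cfg An [rf_config()].
#' @return A `subspace_forest`: list of trees (each with `features` and the
#'   fitted rpart), plus the config.
#' @export
train_rf <- function(x, y, cfg = rf_config()) {
  x <- as.matrix(x)
  y <- as.logical(y)
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to train a forest", call. = FALSE)
  }
  if (cfg$features_per_tree > ncol(x)) {
    stop("features_per_tree exceeds the number of dimensions", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  yf <- factor(y, levels = c(FALSE, TRUE))
  if (cfg$per_split) {
    if (!requireNamespace("ranger", quietly = TRUE)) {
      stop("per_split = TRUE requires the ranger package", call. = FALSE)
    }
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    fit <- ranger::ranger(
      x = x, y = yf, num.trees = cfg$n_trees,
      mtry = cfg$features_per_tree, probability = TRUE,
      min.node.size = 1,
      seed = if (is.null(cfg$seed)) sample.int(.Machine$integer.max, 1)
             else cfg$seed
    )
    return(structure(list(trees = NULL, ranger_fit = fit, config = cfg,
                          n_features = ncol(x)),
                     class = "subspace_forest"))
  }
  ctrl <- rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0, xval = 0,
                               maxsurrogate = 0, usesurrogate = 0,
                               maxcompete = 0)
  trees <- vector("list", cfg$n_trees)
  for (t in seq_len(cfg$n_trees)) {
    feats <- sort(sample.int(ncol(x), cfg$features_per_tree))
    df <- as.data.frame(x[, feats, drop = FALSE])
    names(df) <- paste0("f", feats)
    df$.y <- yf
    fit <- rpart::rpart(.y ~ ., data = df, method = "class", control = ctrl)
    trees[[t]] <- list(features = feats, fit = fit)
  }
  structure(list(trees = trees, config = cfg, n_features = ncol(x)),
            class = "subspace_forest")
}

#' @export
print.subspace_forest <- function(x, ...) {
  cat(sprintf("<subspace_forest> %d trees x %d features (of %d)\n",
              length(x$trees), x$config$features_per_tree, x$n_features))
  invisible(x)
}

#' Forest vote scores
#'
#' The score of a vector is the fraction of trees voting positive, a value
#' on the grid `{0, 1/n_trees, ..., 1}`; the hard label is score > 0.5
#' (majority vote).
#'
#' @param object A `subspace_forest`.
#' @param newdata Feature matrix to score.
#' @param ... Unused.
#' @return Numeric vector of vote fractions.
#' @export
predict.subspace_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$ranger_fit)) {
    colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
    return(predict(object$ranger_fit, newdata)$predictions[, "TRUE"])
  }
  votes <- numeric(nrow(newdata))
  for (tr in object$trees) {
    df <- as.data.frame(newdata[, tr$features, drop = FALSE])
    names(df) <- paste0("f", tr$features)
    cls <- predict(tr$fit, df, type = "class")
    votes <- votes + (cls == "TRUE")
  }
  votes / length(object$trees)
}
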