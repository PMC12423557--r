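#' Class-balancing settings
#'
#' The training protocol: when a GO accession has fewer than
#' `smote_target_positives` positive vectors, positives are oversampled with
#' SMOTE to exactly that target and negatives are left untouched; when
#' positives already reach the target, negatives are instead oversampled to
#' `negative_multiplier` times the positive count.
#'
#' @param smote_target_positives Target positive count (default 1,000).
#' @param negative_multiplier Negative-to-positive ratio used when positives
#'   are plentiful (default 5).
#' @param smote_k_neighbors Number of nearest neighbors used by SMOTE
#'   (default 5).
#' @param rethreshold If `TRUE` (default), synthetic samples are re-binarized
#'   component-wise at 0.5 so the feature space stays 0/1; `FALSE` keeps the
#'   fractional interpolates.
#' @return A `balance_config` list.
#' @export
balance_config <- function(smote_target_positives = 1000,
                           negative_multiplier = 5, smote_k_neighbors = 5,
                           rethreshold = TRUE) {
  stopifnot(smote_target_positives > 0, negative_multiplier > 1,
            smote_k_neighbors >= 1)
  structure(
    list(smote_target_positives = as.integer(smote_target_positives),
         negative_multiplier = negative_multiplier,
         smote_k_neighbors = as.integer(smote_k_neighbors),
         rethreshold = isTRUE(rethreshold)),
    class = "balance_config"
  )
}

#' SMOTE oversampling of a sample matrix
#'
#' Each synthetic sample is a convex combination `x_i + u * (x_j - x_i)`,
#' `u ~ U(0, 1)`, of a uniformly chosen base sample and one of its `k`
#' nearest neighbors (Euclidean) within the same class.
#'
#' @param x Numeric matrix (rows = samples of the class being oversampled).
#' @param n_new Number of synthetic rows to generate.
#' @param k Number of nearest neighbors; silently reduced (with a warning)
#'   when fewer than `k` neighbors exist.
#' @param rethreshold Re-binarize synthetic components at 0.5.
#' @return A `n_new` x `ncol(x)` matrix of synthetic samples.
#' @export
smote <- function(x, n_new, k = 5, rethreshold = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("SMOTE needs at least 2 samples", call. = FALSE)
  if (n_new <= 0L) return(x[0, , drop = FALSE])
  if (k > n - 1L) {
    warning("reducing SMOTE k from ", k, " to ", n - 1L,
            " (too few samples)", call. = FALSE)
    k <- n - 1L
  }
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
  base <- sample.int(n, n_new, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  out <- x[base, , drop = FALSE] + u * (x[pick, , drop = FALSE] -
                                          x[base, , drop = FALSE])
  if (rethreshold) {
    out <- (out >= 0.5) + 0L
    storage.mode(out) <- "integer"
  }
  rownames(out) <- sprintf("synthetic_%04d", seq_len(n_new))
  out
}

#' Balance a positive/negative training set
#'
#' Applies the two-branch protocol of [balance_config()]. Synthetic rows are
#' only ever appended to the minority side of the applicable branch; real
#' rows are never dropped (if negatives already exceed the multiplier target
#' they are left as they are).
#'
#' @param positives,negatives Numeric matrices of class samples.
#' @param cfg A [balance_config()].
#' @param seed Optional RNG seed for reproducible oversampling.
#' @return List with matrices `positives` and `negatives`, and counts
#'   `n_synthetic_positive`, `n_synthetic_negative`.
#' @export
balance <- function(positives, negatives, cfg = balance_config(),
                    seed = NULL) {
  positives <- as.matrix(positives)
  negatives <- as.matrix(negatives)
  if (nrow(positives) < 2L) {
    stop("need at least 2 positive examples to balance", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_pos <- nrow(positives)
  n_neg <- nrow(negatives)
  syn_pos <- 0L
  syn_neg <- 0L
  if (n_pos < cfg$smote_target_positives) {
    syn_pos <- cfg$smote_target_positives - n_pos
    positives <- rbind(positives,
                       smote(positives, syn_pos, cfg$smote_k_neighbors,
                             cfg$rethreshold))
  } else {
    target_neg <- ceiling(cfg$negative_multiplier * n_pos)
    if (n_neg < target_neg) {
      syn_neg <- target_neg - n_neg
      negatives <- rbind(negatives,
                         smote(negatives, syn_neg, cfg$smote_k_neighbors,
                               cfg$rethreshold))
    }
  }
  list(positives = positives, negatives = negatives,
       n_synthetic_positive = syn_pos, n_synthetic_negative = syn_neg)
}
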