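# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# set-based Jaccard index of two binary vectors
jaccard_oracle <- function(a, b) {
  sa <- which(a == 1)
  sb <- which(b == 1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# componentwise loop evaluation of the Tanimoto formula
tanimoto_loop_oracle <- function(a, b) {
  ab <- 0; aa <- 0; bb <- 0
  for (i in seq_along(a)) {
    ab <- ab + a[i] * b[i]
    aa <- aa + a[i]^2
    bb <- bb + b[i]^2
  }
  ab / (aa + bb - ab)
}

# trapezoidal area under the ROC curve, built from scratch
trapezoid_auc_oracle <- function(labels, scores) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), 0)
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# total within-cluster sum of squares of a partition (the Ward objective)
ward_objective_oracle <- function(x, labels) {
  sum(vapply(unique(labels), function(l) {
    xs <- x[labels == l, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, 0))
}

# minimum Ward objective over all 2-partitions of <= 8 points
best_two_partition_oracle <- function(x) {
  n <- nrow(x)
  best <- Inf
  best_labels <- NULL
  for (code in 1:(2^(n - 1) - 1)) { # fix point 1 in cluster 1; skip empty
    labels <- c(1L, as.integer(intToBits(code)[seq_len(n - 1)]) + 1L)
    if (length(unique(labels)) < 2L) next
    obj <- ward_objective_oracle(x, labels)
    if (obj < best) {
      best <- obj
      best_labels <- labels
    }
  }
  list(objective = best, labels = best_labels)
}

# exact two-sided permutation p-value for the Mann-Whitney U statistic
exact_mw_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n))
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, u_of)
  mu <- n * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
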