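#' Tanimoto coefficient between a vector and a centroid
#'
#' The generalized Jaccard similarity
#' \deqn{T(A, B) = \frac{A \cdot B}{\|A\|^2 + \|B\|^2 - A \cdot B}}
#' between a binary fingerprint `a` and a (possibly fractional) positive
#' example mean vector `b`. For two binary vectors it reduces to the set
#' Jaccard index; `T(A, A) = 1` for any nonzero binary vector.
#'
#' @param a Numeric vector (typically 0/1).
#' @param b Numeric vector of the same length, components in \[0, 1\].
#' @return The coefficient, in \[0, 1\] for inputs with components in
#'   \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0) {
    stop("Tanimoto coefficient undefined for two all-zero vectors",
         call. = FALSE)
  }
  ab / denom
}

#' Positive-example centroids per GO accession
#'
#' For each GO accession with at least `min_positive` positive fingerprint
#' vectors, the centroid is the arithmetic mean of those vectors; accessions
#' below the floor are skipped and reported.
#'
#' @param fp A [fingerprint_set()].
#' @param go A [go_table()].
#' @param min_positive Minimum positive vectors (default 3).
#' @param unknown_genes Genes excluded from both classes.
#' @return Tibble with `go_accession`, `n_positive`, and list-column
#'   `centroid`; attribute `skipped` lists accessions below the floor.
#' @export
build_centroids <- function(fp, go, min_positive = 3,
                            unknown_genes = character(0)) {
  labels <- label_vectors(go, fp, unknown_genes)
  keep <- labels$n_positive >= min_positive
  out <- labels[keep, c("go_accession", "n_positive")]
  out$centroid <- lapply(which(keep), function(i) {
    m <- labels$positive[[i]]
    colMeans(fp$bits[which(m), , drop = FALSE])
  })
  attr(out, "skipped") <- labels$go_accession[!keep]
  out
}

#' Classify the separation of positive and negative score distributions
#'
#' Three-way taxonomy of a per-GO score distribution pair:
#' `"indistinguishable"` when a two-sided Mann-Whitney U test cannot separate
#' the samples at level `alpha`; `"separated95"` when it can *and* the
#' empirical overlap coefficient of the two score distributions is at most
#' `overlap_threshold`; `"partial"` otherwise. The overlap coefficient is the
#' shared area of the two normalized score histograms on a common grid.
#'
#' @param scores_positive,scores_negative Numeric score samples (>= 3 each).
#' @param alpha Mann-Whitney significance level.
#' @param overlap_threshold Maximum overlap for the fully separated class.
#' @param n_grid Number of histogram cells on the common grid.
#' @return List with `separation_class`, `mannwhitney_p`, `overlap`.
#' @export
classify_separation <- function(scores_positive, scores_negative,
                                alpha = 0.05, overlap_threshold = 0.05,
                                n_grid = 50) {
  stopifnot(length(scores_positive) >= 3, length(scores_negative) >= 3)
  all_scores <- c(scores_positive, scores_negative)
  if (length(unique(all_scores)) == 1L) {
    warning("all scores tied; classified as indistinguishable", call. = FALSE)
    return(list(separation_class = "indistinguishable", mannwhitney_p = 1,
                overlap = 1))
  }
  exact <- min(length(scores_positive), length(scores_negative)) <= 20 &&
    !anyDuplicated(all_scores)
  p <- suppressWarnings(
    stats::wilcox.test(scores_positive, scores_negative,
                       alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
  brk <- seq(min(all_scores), max(all_scores), length.out = n_grid + 1L)
  brk[1] <- brk[1] - 1e-9
  brk[length(brk)] <- brk[length(brk)] + 1e-9
  hp <- tabulate(findInterval(scores_positive, brk, all.inside = TRUE), n_grid)
  hn <- tabulate(findInterval(scores_negative, brk, all.inside = TRUE), n_grid)
  overlap <- sum(pmin(hp / sum(hp), hn / sum(hn)))
  cls <- if (p >= alpha) "indistinguishable"
         else if (overlap <= overlap_threshold) "separated95"
         else "partial"
  list(separation_class = cls, mannwhitney_p = p, overlap = overlap)
}

#' Tanimoto positive-centroid model over all eligible GO accessions
#'
#' Scores every fingerprint vector against each eligible accession's positive
#' centroid and classifies the separation of the positive and negative score
#' distributions.
#'
#' @param fp A [fingerprint_set()].
#' @param go A [go_table()].
#' @param min_positive Eligibility floor on positive vectors (default 3).
#' @param leave_one_out If `TRUE`, each positive vector is scored against the
#'   centroid of the *other* positives. Default `FALSE`: the centroid
#'   includes the scored vector.
#' @param unknown_genes Genes excluded from both classes.
#' @inheritParams classify_separation
#' @return A `tanimoto_result`: list with `summary` (per-GO tibble:
#'   `go_accession`, `n_positive`, `median_pos_score`, `median_neg_score`,
#'   `mannwhitney_p`, `overlap`, `separation_class`) and `scores` (long
#'   tibble of every vector/GO score with its label).
#' @export
tanimoto_model <- function(fp, go, min_positive = 3, leave_one_out = FALSE,
                           unknown_genes = character(0), alpha = 0.05,
                           overlap_threshold = 0.05) {
  labels <- label_vectors(go, fp, unknown_genes)
  cents <- build_centroids(fp, go, min_positive, unknown_genes)
  rows <- vector("list", nrow(cents))
  scores_long <- vector("list", nrow(cents))
  for (i in seq_len(nrow(cents))) {
    acc <- cents$go_accession[i]
    mask <- labels$positive[[match(acc, labels$go_accession)]]
    use <- !is.na(mask)
    cen <- cents$centroid[[i]]
    n_pos <- cents$n_positive[i]
    sc <- numeric(nrow(fp$bits))
    sc[] <- NA_real_
    for (j in which(use)) {
      b <- cen
      if (leave_one_out && isTRUE(mask[j])) {
        if (n_pos < 2L) next
        b <- (cen * n_pos - fp$bits[j, ]) / (n_pos - 1L)
      }
      sc[j] <- tanimoto(fp$bits[j, ], b)
    }
    pos_sc <- sc[which(use & mask %in% TRUE)]
    neg_sc <- sc[which(use & mask %in% FALSE)]
    pos_sc <- pos_sc[!is.na(pos_sc)]
    cl <- classify_separation(pos_sc, neg_sc, alpha, overlap_threshold)
    rows[[i]] <- tibble::tibble(
      go_accession = acc, n_positive = n_pos,
      median_pos_score = stats::median(pos_sc),
      median_neg_score = stats::median(neg_sc),
      mannwhitney_p = cl$mannwhitney_p, overlap = cl$overlap,
      separation_class = cl$separation_class
    )
    scores_long[[i]] <- tibble::tibble(
      go_accession = acc, spectrum_id = fp$meta$spectrum_id[use],
      label = mask[use], score = sc[use]
    )
  }
  structure(
    list(summary = dplyr::bind_rows(rows),
         scores = dplyr::bind_rows(scores_long),
         min_positive = min_positive, leave_one_out = leave_one_out),
    class = "tanimoto_result"
  )
}

#' @export
print.tanimoto_result <- function(x, ...) {
  counts <- table(factor(x$summary$separation_class,
                         levels = c("indistinguishable", "partial",
                                    "separated95")))
  cat(sprintf(
    "<tanimoto_result> %d GO accessions (floor %d): %d indistinguishable, %d partial, %d separated95\n",
    nrow(x$summary), x$min_positive, counts[1], counts[2], counts[3]
  ))
  invisible(x)
}
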