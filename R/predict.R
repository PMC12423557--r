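#' Matching rules for unknown-genotype strains
#'
#' A gene of unknown function is called a match to a GO accession when every
#' one of its replicate vectors has a positive averaged score *and* the
#' accession was trained on fewer than `max_positive_training_vectors`
#' positives (matching to very large accessions is too frequent to be
#' meaningful). Genes represented by a single spectrum cannot satisfy the
#' duplicate-consistency requirement; with `require_all_replicates = TRUE`
#' (default) they receive a lower-confidence `provisional` flag instead of a
#' match.
#'
#' @param max_positive_training_vectors Strict upper bound on the accession's
#'   positive training count for a match (default 400).
#' @param require_all_replicates Demand every replicate be positive.
#' @param n_models_averaged Number of retained CV models averaged per score
#'   (default 10).
#' @param average_replicates_first If `TRUE`, average replicate scores before
#'   thresholding instead of requiring each replicate to be positive.
#' @return An `unknown_match_config` list.
#' @export
unknown_match_config <- function(max_positive_training_vectors = 400,
                                 require_all_replicates = TRUE,
                                 n_models_averaged = 10,
                                 average_replicates_first = FALSE) {
  stopifnot(max_positive_training_vectors > 0, n_models_averaged > 0)
  structure(
    list(max_positive_training_vectors =
           as.integer(max_positive_training_vectors),
         require_all_replicates = isTRUE(require_all_replicates),
         n_models_averaged = as.integer(n_models_averaged),
         average_replicates_first = isTRUE(average_replicates_first)),
    class = "unknown_match_config"
  )
}

#' Assign GO terms to strains of unknown genotype
#'
#' For every unknown gene and every modeled GO accession, each replicate
#' vector is scored by all retained cross-validation models and the model
#' scores averaged; the gene/GO cell score is the mean over replicates. The
#' match flag applies the duplicate-consistency rule of
#' [unknown_match_config()].
#'
#' @param fp A [fingerprint_set()] containing the unknown strains' vectors
#'   (other vectors may be present; selection is by `unknown_genes`).
#' @param model_set A `go_model_set` from [fit_go_models()] (SVM in the
#'   reference protocol, but any model kind works).
#' @param unknown_genes Character vector of gene ids to score; defaults to
#'   the model set's recorded unknown genes.
#' @param cfg An [unknown_match_config()].
#' @return A `prediction_matrix`: list with `table` (long tibble: `gene_id`,
#'   `go_accession`, `n_replicates`, `score`, `all_replicates_positive`,
#'   `n_positive` ("Size"), `match`, `provisional`) and `config`.
#' @export
predict_unknown <- function(fp, model_set, unknown_genes = NULL,
                            cfg = unknown_match_config()) {
  stopifnot(inherits(fp, "fingerprint_set"),
            inherits(model_set, "go_model_set"))
  if (is.null(unknown_genes)) unknown_genes <- model_set$unknown_genes
  if (length(unknown_genes) == 0L) {
    stop("no unknown genes to score", call. = FALSE)
  }
  groups <- collapse_replicates(fp)
  groups <- groups[names(groups) %in% unknown_genes]
  if (length(groups) == 0L) {
    stop("none of the unknown genes have vectors in the fingerprint set",
         call. = FALSE)
  }
  accs <- names(model_set$results)
  rows <- vector("list", length(groups) * length(accs))
  k <- 0L
  for (g in names(groups)) {
    xg <- fp$bits[groups[[g]], , drop = FALSE]
    for (a in accs) {
      res <- model_set$results[[a]]
      if (length(res$models) < cfg$n_models_averaged) {
        stop("model store for ", a, " holds ", length(res$models),
             " models; ", cfg$n_models_averaged, " required", call. = FALSE)
      }
      per_model <- vapply(res$models[seq_len(cfg$n_models_averaged)],
                          function(m) predict(m, xg), numeric(nrow(xg)))
      rep_scores <- if (nrow(xg) == 1L) mean(per_model)
                    else rowMeans(per_model)
      n_pos <- res$metrics$n_positive
      all_pos <- all(rep_scores > 0)
      mean_score <- mean(rep_scores)
      small_enough <- n_pos < cfg$max_positive_training_vectors
      positive_call <- if (cfg$average_replicates_first) mean_score > 0
                       else all_pos
      single <- nrow(xg) < 2L
      match <- positive_call && small_enough &&
        !(single && cfg$require_all_replicates)
      provisional <- positive_call && small_enough && single &&
        cfg$require_all_replicates
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        gene_id = g, go_accession = a, n_replicates = nrow(xg),
        score = mean_score, all_replicates_positive = all_pos,
        n_positive = n_pos, match = match, provisional = provisional
      )
    }
  }
  structure(list(table = dplyr::bind_rows(rows[seq_len(k)]), config = cfg,
                 model_kind = model_set$model_kind),
            class = "prediction_matrix")
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf(
    "<prediction_matrix> %d genes x %d GO accessions (%s scores): %d matches, %d provisional\n",
    length(unique(x$table$gene_id)), length(unique(x$table$go_accession)),
    x$model_kind, sum(x$table$match), sum(x$table$provisional)
  ))
  invisible(x)
}

#' Export a prediction matrix as a heatmap-ready TSV
#'
#' Writes the gene x GO grid of averaged scores in wide form, with match
#' flags (`*` appended to matched cells) and a `Size` header row carrying
#' each accession's positive training count. Rows are ordered by gene id,
#' columns by GO accession.
#'
#' @param pm A `prediction_matrix` from [predict_unknown()].
#' @param path Output TSV path.
#' @param digits Score rounding for display (default 4).
#' @return The wide tibble, invisibly.
#' @export
export_heatmap_table <- function(pm, path, digits = 4) {
  stopifnot(inherits(pm, "prediction_matrix"), nrow(pm$table) > 0)
  tab <- pm$table |>
    dplyr::arrange(.data$gene_id, .data$go_accession) |>
    dplyr::mutate(cell = paste0(formatC(round(.data$score, digits),
                                        format = "fg"),
                                ifelse(.data$match, "*", "")))
  wide <- tab |>
    dplyr::select("gene_id", "go_accession", "cell") |>
    tidyr::pivot_wider(names_from = "go_accession", values_from = "cell")
  sizes <- tab |>
    dplyr::distinct(.data$go_accession, .data$n_positive) |>
    dplyr::arrange(.data$go_accession)
  size_row <- tibble::as_tibble(
    c(list(gene_id = "Size"),
      stats::setNames(as.list(as.character(sizes$n_positive)),
                      sizes$go_accession))
  )
  out <- dplyr::bind_rows(size_row, wide)
  readr::write_tsv(out, path)
  invisible(out)
}
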