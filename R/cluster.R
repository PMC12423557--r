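#' Ward clustering of binary fingerprint vectors
#'
#' Agglomerative clustering with the classical minimum-variance Ward
#' objective (`ward.D2` on Euclidean distances), cut to a flat partition of
#' `n_clusters` groups. Deterministic for a fixed input; zero-distance pairs
#' merge first, so identical vectors always co-cluster.
#'
#' @param fp A [fingerprint_set()] (or plain 0/1 matrix with row names).
#' @param n_clusters Number of flat clusters (>= 2, <= number of vectors).
#' @return A `ward_clustering`: list with `assignments` (tibble:
#'   `spectrum_id`, `cluster`), the `hclust` tree, and `n_clusters`.
#' @export
ward_cluster <- function(fp, n_clusters = 13) {
  bits <- if (inherits(fp, "fingerprint_set")) fp$bits else as.matrix(fp)
  ids <- rownames(bits)
  if (is.null(ids)) ids <- sprintf("v%04d", seq_len(nrow(bits)))
  if (anyDuplicated(ids)) stop("duplicate spectrum_ids", call. = FALSE)
  stopifnot(n_clusters >= 2, n_clusters <= nrow(bits))
  tree <- stats::hclust(stats::dist(bits, method = "euclidean"),
                        method = "ward.D2")
  labels <- stats::cutree(tree, k = n_clusters)
  structure(
    list(assignments = tibble::tibble(spectrum_id = ids,
                                      cluster = unname(labels)),
         tree = tree, n_clusters = as.integer(n_clusters)),
    class = "ward_clustering"
  )
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> %d vectors in %d clusters (sizes %s)\n",
              nrow(x$assignments), x$n_clusters,
              paste(table(x$assignments$cluster), collapse = "/")))
  invisible(x)
}

#' Export a Ward dendrogram as newick
#'
#' @param clustering A `ward_clustering`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_dendrogram_newick <- function(clustering, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("newick export requires the ape package", call. = FALSE)
  }
  phy <- ape::as.phylo(clustering$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Per-cluster GO fold enrichment
#'
#' Fold enrichment of a GO accession in a cluster is
#' `(matching in cluster / cluster size) / (matching in background /
#' background size)`. GO accessions with zero background matches are skipped
#' with a message (small backgrounds simply lack matches for some terms).
#'
#' @param cluster_genes Character vector of gene ids in one cluster (must be
#'   a subset of `background_genes`).
#' @param go A [go_table()].
#' @param background_genes Character vector of all analyzed gene ids (e.g.
#'   the genes whose products fall under a mass cutoff).
#' @return Tibble with one row per GO accession: `go_accession`,
#'   `n_cluster_genes`, `n_cluster_matching`, `n_background_genes`,
#'   `n_background_matching`, `fold_enrichment`.
#' @export
fold_enrichment <- function(cluster_genes, go, background_genes) {
  stopifnot(inherits(go, "go_table"))
  cluster_genes <- unique(cluster_genes)
  background_genes <- unique(background_genes)
  if (length(cluster_genes) == 0L) stop("empty cluster", call. = FALSE)
  if (!all(cluster_genes %in% background_genes)) {
    stop("cluster genes must be a subset of the background", call. = FALSE)
  }
  n_c <- length(cluster_genes)
  n_b <- length(background_genes)
  rows <- lapply(names(go$genes_by_go), function(a) {
    members <- go$genes_by_go[[a]]
    m_b <- sum(background_genes %in% members)
    if (m_b == 0L) {
      message("skipping ", a, ": no background matches")
      return(NULL)
    }
    m_c <- sum(cluster_genes %in% members)
    tibble::tibble(
      go_accession = a, n_cluster_genes = n_c, n_cluster_matching = m_c,
      n_background_genes = n_b, n_background_matching = m_b,
      fold_enrichment = (m_c / n_c) / (m_b / n_b)
    )
  })
  dplyr::bind_rows(rows)
}

#' Fold enrichment for every cluster of a Ward partition
#'
#' @param clustering A `ward_clustering`.
#' @param fp The [fingerprint_set()] that was clustered (maps spectra to
#'   genes).
#' @param go A [go_table()].
#' @param background_genes Background gene set; defaults to all genes in
#'   `fp`.
#' @return Tibble of [fold_enrichment()] rows with a leading `cluster`
#'   column.
#' @export
cluster_enrichment <- function(clustering, fp, go, background_genes = NULL) {
  stopifnot(inherits(clustering, "ward_clustering"),
            inherits(fp, "fingerprint_set"))
  if (is.null(background_genes)) background_genes <- unique(fp$meta$gene_id)
  joined <- dplyr::left_join(clustering$assignments, fp$meta,
                             by = "spectrum_id")
  purrr::map_dfr(sort(unique(joined$cluster)), function(cl) {
    genes <- unique(joined$gene_id[joined$cluster == cl])
    fold_enrichment(genes, go, background_genes) |>
      dplyr::mutate(cluster = cl, .before = 1L)
  })
}
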