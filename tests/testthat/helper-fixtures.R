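# Small in-code fixtures shared across tests.

# a spectrum with a dense low-intensity floor plus tall peaks at given m/z
peaky_spectrum <- function(peak_mz, peak_intensity = 5000, n_floor = 600,
                          id = "s1", gene = "geneA", replicate = 1L,
                          seed = 99L) {
  set.seed(seed)
  mz <- c(runif(n_floor, 3000, 20000), peak_mz)
  intensity <- c(rlnorm(n_floor, 0, 0.3),
                 rep_len(peak_intensity, length(peak_mz)))
  ord <- order(mz)
  mass_spectrum(mz[ord], intensity[ord], id, gene, replicate)
}

# a fingerprint set with planted block structure: each block of genes shares
# a distinct set of on-bins
block_fingerprints <- function(n_genes_per_block = 4, n_blocks = 2,
                               n_bins = 40, bits_per_block = 8,
                               replicates = 1L, seed = 5L) {
  set.seed(seed)
  stopifnot(n_blocks * bits_per_block <= n_bins)
  rows <- list()
  meta <- list()
  k <- 0L
  for (b in seq_len(n_blocks)) {
    on <- ((b - 1L) * bits_per_block + 1L):(b * bits_per_block)
    for (g in seq_len(n_genes_per_block)) {
      gene <- sprintf("blk%d_gene%d", b, g)
      for (r in seq_len(replicates)) {
        k <- k + 1L
        v <- integer(n_bins)
        v[on] <- 1L
        rows[[k]] <- v
        meta[[k]] <- tibble::tibble(
          spectrum_id = sprintf("%s_r%d", gene, r),
          gene_id = gene, replicate = r
        )
      }
    }
  }
  fingerprint_set(do.call(rbind, rows), dplyr::bind_rows(meta),
                  digitization_config(window_low = 0, window_high = n_bins,
                                      bin_width = 1))
}

# annotation table assigning each block's genes to one GO term
block_go <- function(fp) {
  genes <- unique(fp$meta$gene_id)
  blocks <- sub("_gene\\d+$", "", genes)
  ids <- sprintf("GO:%07d", as.integer(factor(blocks)))
  go_table(tibble::tibble(gene_id = genes, go_accession = ids))
}

# a stub model whose score is a fixed linear read-out of the first feature,
# registered so predict() dispatch works inside tests
make_stub_model <- function(scale = 2, offset = -1) {
  structure(list(scale = scale, offset = offset), class = "stub_margin_model")
}
predict.stub_margin_model <- function(object, newdata, ...) {
  as.matrix(newdata)[, 1] * object$scale + object$offset
}
registerS3method("predict", "stub_margin_model", predict.stub_margin_model,
                 envir = asNamespace("stats"))

# a minimal go_model_set around stub models, for exercising the matching rule
stub_model_set <- function(accessions, n_positive, unknown_genes,
                           n_models = 10) {
  results <- lapply(seq_along(accessions), function(i) {
    list(models = replicate(n_models, make_stub_model(), simplify = FALSE),
         metrics = tibble::tibble(n_positive = n_positive[i]))
  })
  names(results) <- accessions
  structure(list(results = results, model_kind = "svm",
                 unknown_genes = unknown_genes),
            class = "go_model_set")
}
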