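test_that("Ward clustering recovers planted blocks and matches the brute-force optimum", {
  fp <- block_fingerprints(n_genes_per_block = 4, n_blocks = 2, seed = 5)
  cl <- ward_cluster(fp, 2)
  labels <- cl$assignments$cluster
  truth <- rep(1:2, each = 4)
  # partition equality up to label swap
  expect_true(all(table(labels, truth) %in% c(0L, 4L)))
  # the cut achieves the exhaustive minimum of the Ward objective (<= 8 points)
  best <- best_two_partition_oracle(fp$bits)
  expect_equal(ward_objective_oracle(fp$bits, labels), best$objective)
})

test_that("degenerate cuts behave: singletons and identical-vector co-clustering", {
  fp <- block_fingerprints(n_genes_per_block = 3, n_blocks = 2, seed = 6)
  n <- nrow(fp$bits)
  singletons <- ward_cluster(fp, n)
  expect_identical(sort(unique(singletons$assignments$cluster)), 1:n)
  # an identical pair among otherwise distinct vectors co-clusters at any
  # cut below n (the zero-distance merge happens first)
  set.seed(6)
  distinct <- do.call(rbind, lapply(1:5, function(i) {
    v <- integer(30)
    v[((i - 1) * 6 + 1):(i * 6)] <- 1L
    v
  }))
  x <- rbind(distinct, distinct[1, ])
  rownames(x) <- sprintf("s%d", 1:6)
  for (k in 2:5) {
    lab <- ward_cluster(x, k)$assignments$cluster
    expect_identical(lab[1], lab[6])
  }
  dup <- fp
  dup$meta$spectrum_id[2] <- dup$meta$spectrum_id[1]
  rownames(dup$bits)[2] <- rownames(dup$bits)[1]
  expect_error(ward_cluster(dup$bits, 2), "duplicate")
})

test_that("cluster labels form a partition", {
  fp <- block_fingerprints(n_genes_per_block = 5, n_blocks = 3, n_bins = 60,
                           seed = 7)
  cl <- ward_cluster(fp, 3)
  expect_identical(nrow(cl$assignments), nrow(fp$bits))
  expect_identical(anyDuplicated(cl$assignments$spectrum_id), 0L)
  expect_identical(sort(unique(cl$assignments$cluster)), 1:3)
})

test_that("fold enrichment evaluates the printed equation", {
  go <- go_table(tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    go_accession = "GO:0000001"
  ))
  background <- sprintf("g%02d", 1:100)
  # cluster: 4 genes, 2 matching; background: 100 genes, 10 matching
  res <- fold_enrichment(c("g01", "g02", "g50", "g60"), go, background)
  expect_equal(res$fold_enrichment, (2 / 4) / (10 / 100))
  expect_equal(res$fold_enrichment, 5.0)
  expect_identical(res$n_cluster_matching, 2L)
  expect_identical(res$n_background_matching, 10L)

  # null enrichment: cluster mirrors the background proportion
  null <- fold_enrichment(c("g01", sprintf("g%02d", 11:19)), go, background)
  expect_equal(null$fold_enrichment, 1.0)
  # zero matching in cluster
  zero <- fold_enrichment(sprintf("g%02d", 51:54), go, background)
  expect_equal(zero$fold_enrichment, 0.0)

  expect_error(fold_enrichment(character(0), go, background), "empty")
  expect_error(fold_enrichment("not_there", go, background), "subset")
  # zero background matches: term skipped with a message
  go2 <- go_table(tibble::tibble(gene_id = c("g01", "zzz"),
                                 go_accession = c("GO:0000001", "GO:0000002")))
  expect_message(res2 <- fold_enrichment("g01", go2, background), "skipping")
  expect_identical(res2$go_accession, "GO:0000001")
})

test_that("fold enrichment is invariant to gene relabeling", {
  genes <- sprintf("g%02d", 1:20)
  go <- go_table(tibble::tibble(gene_id = genes[1:6],
                                go_accession = "GO:0000009"))
  a <- fold_enrichment(genes[c(1, 2, 10, 11)], go, genes)
  relabel <- setNames(sprintf("x%02d", 1:20), genes)
  go2 <- go_table(tibble::tibble(gene_id = relabel[genes[1:6]],
                                 go_accession = "GO:0000009"))
  b <- fold_enrichment(relabel[genes[c(1, 2, 10, 11)]], go2, relabel)
  expect_equal(a$fold_enrichment, b$fold_enrichment)
})

test_that("top-enriched GO per cluster recovers the dominant planted term", {
  # one dominant GO signature per block, penetrance 0.9, bin noise 0.02
  set.seed(33)
  n_blocks <- 4
  genes_per_block <- 15
  n_bins <- 120
  p <- 0.9
  q <- 0.02
  rows <- list()
  genes <- character(0)
  for (b in seq_len(n_blocks)) {
    sig <- ((b - 1) * 15 + 1):(b * 15)
    for (g in seq_len(genes_per_block)) {
      v <- integer(n_bins)
      v[101:120] <- 1L                        # shared baseline bins
      v[sig] <- rbinom(15, 1, p)              # block signature
      flip <- runif(n_bins) < q
      v[flip] <- 1L - v[flip]
      gene <- sprintf("blk%d_g%02d", b, g)
      genes <- c(genes, gene)
      rows[[length(rows) + 1L]] <- v
    }
  }
  fp <- fingerprint_set(
    do.call(rbind, rows),
    tibble::tibble(spectrum_id = paste0(genes, "_r1"), gene_id = genes,
                   replicate = 1L),
    digitization_config(0, n_bins, 1)
  )
  go <- go_table(tibble::tibble(
    gene_id = genes,
    go_accession = sprintf("GO:%07d", rep(seq_len(n_blocks),
                                          each = genes_per_block))
  ))
  cl <- ward_cluster(fp, n_blocks)
  enr <- cluster_enrichment(cl, fp, go)
  joined <- dplyr::left_join(cl$assignments, fp$meta, by = "spectrum_id")
  recovered <- 0L
  for (k in sort(unique(cl$assignments$cluster))) {
    top <- enr |>
      dplyr::filter(.data$cluster == k) |>
      dplyr::slice_max(.data$fold_enrichment, n = 1, with_ties = FALSE)
    genes_k <- joined$gene_id[joined$cluster == k]
    modal <- names(sort(table(go$pairs$go_accession[
      go$pairs$gene_id %in% genes_k]), decreasing = TRUE))[1]
    if (identical(top$go_accession, modal)) recovered <- recovered + 1L
  }
  expect_gte(recovered / n_blocks, 0.9)
})

test_that("dendrograms export as readable newick", {
  fp <- block_fingerprints(n_genes_per_block = 3, n_blocks = 2, seed = 8)
  cl <- ward_cluster(fp, 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram_newick(cl, path)
  phy <- ape::read.tree(path)
  expect_identical(sort(phy$tip.label), sort(fp$meta$spectrum_id))
})
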