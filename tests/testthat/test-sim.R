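test_that("fixed seed gives bit-identical libraries", {
  cfg <- sim_config(n_genes = 10, n_go_terms = 2, genes_per_go = c(3, 5),
                    baseline_peaks = 80, signature_bins_per_go = 8,
                    seed = 123)
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  expect_identical(a$planted_bits, b$planted_bits)
  expect_identical(a$truth_annotations$pairs, b$truth_annotations$pairs)
  expect_identical(a$planted_signatures, b$planted_signatures)
  expect_identical(a$spectra, b$spectra)
})

test_that("noiseless limit: knockouts differ from baseline exactly on their signature bins", {
  cfg <- sim_config(n_genes = 12, n_go_terms = 3, genes_per_go = c(3, 4),
                    baseline_peaks = 90, signature_bins_per_go = 10,
                    bin_noise_rate = 0, signature_penetrance = 1,
                    replicates_per_strain = 1, gene_loss_bins = 0, seed = 11)
  lib <- simulate_library(cfg)
  fp <- digitize_library(lib$spectra)
  expect_identical(unname(fp$bits), unname(lib$planted_bits))

  baseline <- rep(0L, 1700)
  baseline[lib$baseline_bins + 1L] <- 1L
  pairs <- lib$truth_annotations$pairs
  for (i in seq_len(nrow(fp$bits))) {
    gene <- fp$meta$gene_id[i]
    gos <- pairs$go_accession[pairs$gene_id == gene]
    expected_diff <- sort(unique(unlist(lib$planted_signatures[gos]))) + 1L
    observed_diff <- which(fp$bits[i, ] != baseline)
    expect_identical(unname(observed_diff), expected_diff)
  }
})

test_that("empirical flip frequency at non-signature bins matches the noise rate", {
  q <- 0.02
  cfg <- sim_config(n_genes = 100, n_go_terms = 5, genes_per_go = c(10, 20),
                    baseline_peaks = 150, signature_bins_per_go = 10,
                    signature_penetrance = 0.9, bin_noise_rate = q,
                    replicates_per_strain = 1, gene_loss_bins = 0, seed = 21)
  lib <- simulate_library(cfg)
  fp <- digitize_library(lib$spectra)
  sig_bins <- unlist(lib$planted_signatures) + 1L
  keep <- setdiff(seq_len(1700), sig_bins)
  # brute-force tally of disagreements with the planted state over all vectors
  flips <- 0L
  cells <- 0L
  for (i in seq_len(nrow(fp$bits))) {
    flips <- flips + sum(fp$bits[i, keep] != lib$planted_bits[i, keep])
    cells <- cells + length(keep)
  }
  ci <- qbinom(c(0.0005, 0.9995), cells, q) / cells
  expect_gte(flips / cells, ci[1])
  expect_lte(flips / cells, ci[2])
})

test_that("unrecoverable regimes and oversized signature requests are rejected", {
  expect_error(sim_config(signature_penetrance = 0.01, bin_noise_rate = 0.05),
               "unrecoverable")
  expect_warning(sim_config(signature_penetrance = 0.01,
                            bin_noise_rate = 0.05, strict = FALSE),
                 "unrecoverable")
  cfg <- sim_config(n_go_terms = 200, signature_bins_per_go = 10,
                    baseline_peaks = 1700, seed = 1)
  expect_error(simulate_library(cfg), "signature")
})

test_that("make_unknown_set strips the exact count and keeps truth recoverable", {
  cfg <- sim_config(n_genes = 100, n_go_terms = 4, genes_per_go = c(20, 30),
                    baseline_peaks = 120, signature_bins_per_go = 10,
                    seed = 31)
  lib <- simulate_library(cfg)

  lib0 <- make_unknown_set(lib, 0)
  expect_length(lib0$unknown_genes, 0)
  expect_identical(nrow(lib0$hidden_truth), 0L)

  lib10 <- make_unknown_set(lib, 0.1)
  expect_length(lib10$unknown_genes, 10)
  # stripped genes' vectors absent from every training positive set
  fp <- digitize_library(lib10$spectra)
  labels <- label_vectors(lib10$truth_annotations, fp, lib10$unknown_genes)
  for (i in seq_len(nrow(labels))) {
    mask <- labels$positive[[i]]
    pos_genes <- fp$meta$gene_id[which(mask)]
    expect_length(intersect(pos_genes, lib10$unknown_genes), 0)
  }
  # hidden truth and remaining truth partition the original pairs
  recombined <- dplyr::bind_rows(lib10$truth_annotations$pairs,
                                 lib10$hidden_truth)
  expect_setequal(paste(recombined$gene_id, recombined$go_accession),
                  paste(lib$truth_annotations$pairs$gene_id,
                        lib$truth_annotations$pairs$go_accession))
})

test_that("make_unknown_set refuses to empty a GO term of positives", {
  cfg <- sim_config(n_genes = 3, n_go_terms = 1, genes_per_go = c(1, 1),
                    baseline_peaks = 40, signature_bins_per_go = 4, seed = 41)
  lib <- simulate_library(cfg)
  lib$truth_annotations <- go_table(tibble::tibble(
    gene_id = c("gene0001", "gene0002", "gene0003"),
    go_accession = c("GO:0000001", "GO:0000002", "GO:0000003")
  ))
  expect_error(make_unknown_set(lib, 0.67), "zero positives")
})

test_that("every strain has exactly replicates_per_strain spectra", {
  cfg <- sim_config(n_genes = 7, n_go_terms = 2, genes_per_go = c(2, 3),
                    baseline_peaks = 60, signature_bins_per_go = 5,
                    replicates_per_strain = 3, seed = 51)
  lib <- simulate_library(cfg)
  counts <- table(lib$strain_table$gene_id)
  expect_true(all(counts == 3))
  expect_length(lib$spectra, 21)
})

test_that("stronger signature penetrance never hurts recoverability in expectation", {
  mean_auc <- function(p, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- sim_config(n_genes = 40, n_go_terms = 3, genes_per_go = c(8, 12),
                        baseline_peaks = 120, signature_bins_per_go = 12,
                        signature_penetrance = p, bin_noise_rate = 0.02,
                        replicates_per_strain = 1, seed = s)
      lib <- simulate_library(cfg)
      fp <- digitize_library(lib$spectra)
      res <- tanimoto_model(fp, lib$truth_annotations)
      sc <- res$scores
      mean(vapply(unique(sc$go_accession), function(a) {
        sub <- sc[sc$go_accession == a, ]
        auc(sub$label, sub$score)
      }, 0))
    }, 0))
  }
  seeds <- 61:63
  expect_gte(mean_auc(0.9, seeds), mean_auc(0.3, seeds))
})
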