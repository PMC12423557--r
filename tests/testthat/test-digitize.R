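test_that("standard scores match the hand-computed z-score example", {
  # intensities (0, 0, 0, 10): mean 2.5, population sd ~4.3301
  z <- standard_scores(c(0, 0, 0, 10), reference = "global")
  expect_equal(z[4], (10 - 2.5) / sqrt(mean((c(0, 0, 0, 10) - 2.5)^2)))
  expect_equal(round(z[4], 4), 1.7321)

  # identity: mean 0, population sd 1
  set.seed(1)
  y <- rlnorm(200)
  zg <- standard_scores(y, reference = "global")
  expect_equal(mean(zg), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(zg^2)), 1, tolerance = 1e-12)

  expect_warning(z0 <- standard_scores(rep(4, 10)), "zero")
  expect_equal(z0, rep(0, 10))
})

test_that("digitization yields the canonical partition and respects thresholds", {
  cfg <- digitization_config()
  expect_identical(n_bins(cfg), 1700L)
  expect_error(digitization_config(window_high = 20005), "divisible")

  s <- peaky_spectrum(4505)
  v <- digitize(s, cfg)
  expect_length(v, 1700)
  expect_identical(unname(which(v == 1L)), 151L) # 0-based bin 150

  # all scores below threshold -> all-zero vector
  low <- peaky_spectrum(c(5000, 9000), peak_intensity = 1.5)
  expect_identical(sum(digitize(low, cfg)), 0L)
})

test_that("peak-to-bin assignment agrees with an exhaustive interval oracle", {
  cfg <- digitization_config()
  set.seed(7)
  mz <- runif(300, 2900, 20100)
  edges_low <- cfg$window_low + (0:1699) * cfg$bin_width
  for (m in mz) {
    s <- peaky_spectrum(m, n_floor = 400, seed = 3)
    v <- digitize(s, cfg)
    # brute force: test membership of m in every candidate interval
    member <- which(m >= edges_low & m < edges_low + cfg$bin_width)
    expect_identical(unname(which(v == 1L)), member)
  }
})

test_that("peak order never affects the fingerprint", {
  s <- peaky_spectrum(c(3501, 7203, 15999), seed = 13)
  set.seed(2)
  perm <- sample(nrow(s))
  s2 <- suppressWarnings(
    mass_spectrum(s$mz[perm], s$intensity[perm], "s2")
  )
  expect_identical(as.vector(digitize(s)), as.vector(digitize(s2)))
})

test_that("TSV and mzML spectrum IO round-trips, sorting descending input", {
  s <- peaky_spectrum(c(5005, 12345), n_floor = 50, seed = 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, tsv)
  s2 <- read_spectrum(tsv, spectrum_id = attr(s, "spectrum_id"))
  expect_equal(s2$mz, s$mz, tolerance = 1e-12)
  expect_equal(s2$intensity, s$intensity, tolerance = 1e-12)

  # descending input sorted with a warning
  desc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("4000\t500", "3005\t10"), desc)
  expect_warning(s3 <- read_spectrum(desc), "sorting")
  expect_equal(s3$mz, c(3005, 4000))
  expect_equal(s3$intensity, c(10, 500))

  # simple two-row contract
  two <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "3005\t10", "4000\t500"), two)
  expect_identical(nrow(read_spectrum(two)), 2L)
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing", empty)
  expect_error(read_spectrum(empty), "empty|unparseable")

  ml <- withr::local_tempfile(fileext = ".mzML")
  write_spectrum(s, ml, format = "mzml")
  s4 <- read_spectrum(ml, format = "mzml")
  expect_equal(s4$mz, s$mz, tolerance = 1e-6)
  expect_equal(s4$intensity, s$intensity, tolerance = 1e-4)
})

test_that("fingerprint TSV dialects round-trip bit-exactly and digitization is idempotent", {
  lib <- simulate_library(sim_config(n_genes = 6, n_go_terms = 2,
                                     genes_per_go = c(2, 3),
                                     baseline_peaks = 60,
                                     signature_bins_per_go = 6, seed = 3))
  fp <- digitize_library(lib$spectra)
  for (dialect in c("wide", "bits")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_fingerprints(fp, path, dialect)
    fp2 <- read_fingerprints(path)
    expect_identical(unname(fp2$bits), unname(fp$bits))
    expect_identical(fp2$meta$spectrum_id, fp$meta$spectrum_id)
  }
  # re-digitizing a spectrum re-read from its own serialization is stable
  p <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(lib$spectra[[1]], p)
  s2 <- read_spectrum(p, spectrum_id = "x")
  expect_identical(as.vector(digitize(s2)), as.vector(digitize(lib$spectra[[1]])))
})

test_that("replicate grouping is lossless and rejects orphans", {
  bits <- matrix(0L, 7, 10)
  bits[, 1] <- 1L
  meta <- tibble::tibble(
    spectrum_id = sprintf("s%d", 1:7),
    gene_id = c("X", "X", "Y", "Z", "Z", "Z", "Z"),
    replicate = c(1L, 2L, 1L, 1L, 2L, 3L, 4L)
  )
  fp <- fingerprint_set(bits, meta,
                        digitization_config(0, 10, 1))
  groups <- collapse_replicates(fp)
  expect_identical(lengths(groups), c(X = 2L, Y = 1L, Z = 4L))
  # vectors are grouped, never merged: indices recover the originals
  expect_identical(sort(unlist(groups, use.names = FALSE)), 1:7)

  bad_table <- meta[1:5, ]
  expect_error(collapse_replicates(fp, bad_table), "s6")
})
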