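#' Simulation settings for a synthetic knockout library
#'
#' The generator emulates the data regime of a whole-cell MALDI-TOF screen of
#' a single-gene knockout collection: a shared wild-type baseline of tall
#' peaks, GO-term-correlated signature bins lost in knockouts of member genes,
#' a gene-specific lost peak per strain (the knocked-out product), duplicate
#' spotting, multiplicative log-normal intensity noise and a low-intensity
#' noise floor.
#'
#' Each "on" fingerprint bin receives one tall peak at the bin center plus
#' m/z jitter; each spectrum additionally receives `noise_points` low
#' intensity floor samples spread uniformly over the window, which anchor the
#' noise-floor standard-score reference used at digitization.
#'
#' @param n_genes Number of knockout strains.
#' @param n_go_terms Number of planted GO terms.
#' @param genes_per_go Length-2 integer range; each term's member count is
#'   drawn uniformly from it.
#' @param baseline_peaks Number of bins on in every wild-type-like spectrum.
#' @param signature_bins_per_go Bins per GO term whose state flips in member
#'   knockouts.
#' @param signature_penetrance Probability `p` that a signature bin is flipped
#'   in a given member-knockout spectrum.
#' @param bin_noise_rate Probability `q` that any bin's state flips due to
#'   noise. Recoverable simulations need `p > q`.
#' @param replicates_per_strain Spectra per strain (default 2: duplicate
#'   spotting).
#' @param gene_loss_bins Baseline bins additionally lost (with probability
#'   `p`) in each single strain, emulating loss of that gene's own product.
#' @param peak_mz_jitter Uniform m/z jitter (Th) applied to each planted peak
#'   around its bin center; clamped so peaks stay inside their bin.
#' @param intensity_lognormal_sigma Log-sd of planted peak intensities.
#' @param peak_intensity_meanlog Log-mean of planted peak intensities.
#' @param noise_points Floor samples per spectrum.
#' @param unannotated_fraction Fraction of genes carrying no GO annotation at
#'   all (never members of any term).
#' @param seed Integer RNG seed; fixed seed gives bit-identical libraries.
#' @param strict If `TRUE`, error when `p <= q` (unrecoverable regime);
#'   otherwise warn.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 100, n_go_terms = 8,
                       genes_per_go = c(15, 30), baseline_peaks = 300,
                       signature_bins_per_go = 30, signature_penetrance = 0.9,
                       bin_noise_rate = 0.02, replicates_per_strain = 2,
                       gene_loss_bins = 1, peak_mz_jitter = 2,
                       intensity_lognormal_sigma = 0.3,
                       peak_intensity_meanlog = log(5000),
                       noise_points = 1500, unannotated_fraction = 0,
                       seed = 1L, strict = TRUE) {
  p <- signature_penetrance
  q <- bin_noise_rate
  stopifnot(p >= 0, p <= 1, q >= 0, q <= 1, n_genes >= 1, n_go_terms >= 1,
            baseline_peaks >= 1, signature_bins_per_go >= 1,
            replicates_per_strain >= 1, length(genes_per_go) == 2,
            genes_per_go[1] >= 1, genes_per_go[2] >= genes_per_go[1],
            unannotated_fraction >= 0, unannotated_fraction < 1)
  if (p <= q) {
    msg <- sprintf("signature_penetrance (%.3g) <= bin_noise_rate (%.3g): unrecoverable regime", p, q)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), n_go_terms = as.integer(n_go_terms),
         genes_per_go = as.integer(genes_per_go),
         baseline_peaks = as.integer(baseline_peaks),
         signature_bins_per_go = as.integer(signature_bins_per_go),
         signature_penetrance = p, bin_noise_rate = q,
         replicates_per_strain = as.integer(replicates_per_strain),
         gene_loss_bins = as.integer(gene_loss_bins),
         peak_mz_jitter = peak_mz_jitter,
         intensity_lognormal_sigma = intensity_lognormal_sigma,
         peak_intensity_meanlog = peak_intensity_meanlog,
         noise_points = as.integer(noise_points),
         unannotated_fraction = unannotated_fraction,
         seed = as.integer(seed), strict = isTRUE(strict)),
    class = "sim_config"
  )
}

go_accession_ids <- function(n) sprintf("GO:%07d", seq_len(n))

#' Simulate a knockout library with planted GO signature structure
#'
#' Generates spectra, truth annotations and the planted signature map. For a
#' fixed seed the output is bit-identical across calls. Signature bins are
#' drawn without replacement globally (disjoint across GO terms) from the
#' baseline peak set, so member knockouts *lose* signature peaks, mirroring
#' lost gene products. Every bin state then flips with probability
#' `bin_noise_rate` independently per spectrum.
#'
#' @param config A [sim_config()].
#' @param digitization The [digitization_config()] the spectra are meant to
#'   be digitized under (defines the bin grid the generator plants on).
#' @return A `sim_library`: list with `spectra` (list of [mass_spectrum()]),
#'   `strain_table` (tibble), `truth_annotations` (a [go_table()]),
#'   `planted_signatures` (named list GO -> 0-based bin indices),
#'   `planted_bits` (integer matrix: the noise-free expected fingerprint of
#'   every spectrum), `baseline_bins`, `config`.
#' @export
simulate_library <- function(config = sim_config(),
                             digitization = digitization_config()) {
  stopifnot(inherits(config, "sim_config"))
  nb <- digitization$n_bins
  need <- config$n_go_terms * config$signature_bins_per_go
  if (need > nb) {
    stop(sprintf("requested %d signature bins but only %d bins exist",
                 need, nb), call. = FALSE)
  }
  if (need + config$gene_loss_bins > config$baseline_peaks) {
    stop("baseline_peaks too small to host all GO signatures plus gene-specific losses",
         call. = FALSE)
  }
  if (config$baseline_peaks > nb) stop("baseline_peaks exceeds bin count", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  go_ids <- go_accession_ids(config$n_go_terms)

  baseline <- sort(sample.int(nb, config$baseline_peaks)) # 1-based bins
  sig_pool <- sample(baseline) # shuffled; signatures disjoint across terms
  signatures <- vector("list", config$n_go_terms)
  names(signatures) <- go_ids
  for (g in seq_len(config$n_go_terms)) {
    take <- seq.int((g - 1L) * config$signature_bins_per_go + 1L,
                    g * config$signature_bins_per_go)
    signatures[[g]] <- sort(sig_pool[take])
  }
  sig_bins_all <- unlist(signatures, use.names = FALSE)

  n_unannot <- floor(config$unannotated_fraction * config$n_genes)
  annotatable <- if (n_unannot > 0) {
    setdiff(genes, sample(genes, n_unannot))
  } else genes

  pairs <- purrr::map_dfr(seq_len(config$n_go_terms), function(g) {
    size <- sample(seq.int(config$genes_per_go[1], config$genes_per_go[2]), 1L)
    size <- min(size, length(annotatable))
    tibble::tibble(gene_id = sample(annotatable, size), go_accession = go_ids[g])
  })

  # per-gene specific loss bins, outside all signatures
  loss_pool <- setdiff(baseline, sig_bins_all)
  gene_loss <- lapply(seq_len(config$n_genes), function(i) {
    if (config$gene_loss_bins == 0L || length(loss_pool) == 0L) integer(0)
    else sample(loss_pool, min(config$gene_loss_bins, length(loss_pool)))
  })
  names(gene_loss) <- genes

  member_bins <- lapply(genes, function(g) {
    gos <- pairs$go_accession[pairs$gene_id == g]
    sort(unique(c(unlist(signatures[gos], use.names = FALSE), gene_loss[[g]])))
  })
  names(member_bins) <- genes

  n_spec <- config$n_genes * config$replicates_per_strain
  planted_bits <- matrix(0L, n_spec, nb,
                         dimnames = list(NULL, sprintf("bin_%04d", 0:(nb - 1L))))
  spectra <- vector("list", n_spec)
  strain <- tibble::tibble(spectrum_id = character(n_spec),
                           gene_id = character(n_spec),
                           replicate = integer(n_spec))
  centers <- digitization$window_low +
    (seq_len(nb) - 0.5) * digitization$bin_width
  jitter_cap <- max(0, min(config$peak_mz_jitter,
                           digitization$bin_width / 2 - 0.5))

  k <- 0L
  for (i in seq_along(genes)) {
    target <- rep(0L, nb)
    target[baseline] <- 1L
    target[member_bins[[i]]] <- 0L # fully penetrant expected state
    for (r in seq_len(config$replicates_per_strain)) {
      k <- k + 1L
      state <- rep(0L, nb)
      state[baseline] <- 1L
      flip_sig <- member_bins[[i]][
        stats::runif(length(member_bins[[i]])) < config$signature_penetrance]
      state[flip_sig] <- 0L
      noise_flip <- which(stats::runif(nb) < config$bin_noise_rate)
      state[noise_flip] <- 1L - state[noise_flip]
      on_bins <- which(state == 1L)

      mz_peaks <- centers[on_bins] +
        stats::runif(length(on_bins), -jitter_cap, jitter_cap)
      int_peaks <- stats::rlnorm(length(on_bins),
                                 meanlog = config$peak_intensity_meanlog,
                                 sdlog = config$intensity_lognormal_sigma)
      mz_floor <- stats::runif(config$noise_points,
                               digitization$window_low,
                               digitization$window_high)
      int_floor <- stats::rlnorm(config$noise_points, 0, 0.3)
      sid <- sprintf("%s_r%d", genes[i], r)
      mz_all <- c(mz_peaks, mz_floor)
      int_all <- c(int_peaks, int_floor)
      ord <- order(mz_all)
      spectra[[k]] <- mass_spectrum(mz_all[ord], int_all[ord],
                                    spectrum_id = sid, gene_id = genes[i],
                                    replicate = r)
      planted_bits[k, ] <- target
      strain$spectrum_id[k] <- sid
      strain$gene_id[k] <- genes[i]
      strain$replicate[k] <- r
    }
  }

  rownames(planted_bits) <- strain$spectrum_id

  structure(
    list(spectra = spectra, strain_table = strain,
         truth_annotations = go_table(pairs),
         planted_signatures = lapply(signatures, function(b) b - 1L),
         planted_bits = planted_bits,
         baseline_bins = baseline - 1L,
         unknown_genes = character(0),
         hidden_truth = NULL,
         config = config, digitization = digitization),
    class = "sim_library"
  )
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf(
    "<sim_library> %d spectra / %d genes; %d GO terms; %d unknown genes\n",
    length(x$spectra), x$config$n_genes, x$config$n_go_terms,
    length(x$unknown_genes)
  ))
  invisible(x)
}

#' Hide the annotations of a random gene subset
#'
#' Emulates strains of unknown genotype: the selected genes keep their
#' spectra (signatures present) but their annotations are removed from the
#' training truth and returned separately for recovery scoring.
#'
#' @param lib A `sim_library` from [simulate_library()].
#' @param fraction Fraction of genes to strip, in (0, 1); 0 is a no-op.
#' @param seed RNG seed for the subset draw.
#' @return The library with `truth_annotations` reduced, `unknown_genes` set,
#'   and `hidden_truth` (a tibble of the stripped gene/GO pairs).
#' @export
make_unknown_set <- function(lib, fraction, seed = lib$config$seed + 1L) {
  stopifnot(inherits(lib, "sim_library"), fraction >= 0, fraction < 1)
  n_strip <- floor(fraction * lib$config$n_genes)
  if (n_strip == 0L) {
    lib$hidden_truth <- lib$truth_annotations$pairs[0, ]
    return(lib)
  }
  pairs <- lib$truth_annotations$pairs
  genes <- sort(unique(lib$strain_table$gene_id))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  picked <- NULL
  for (try in seq_len(100L)) {
    cand <- sample(genes, n_strip)
    left <- pairs[!pairs$gene_id %in% cand, ]
    if (all(table(factor(left$go_accession,
                         levels = unique(pairs$go_accession))) > 0L)) {
      picked <- cand
      break
    }
  }
  if (is.null(picked)) {
    stop("stripping ", n_strip,
         " genes would leave a GO term with zero positives", call. = FALSE)
  }
  lib$unknown_genes <- sort(picked)
  lib$hidden_truth <- pairs[pairs$gene_id %in% picked, ]
  lib$truth_annotations <- go_table(pairs[!pairs$gene_id %in% picked, ])
  lib
}

#' Write a simulated library to disk
#'
#' Writes one TSV peak list per spectrum under `dir/spectra/`, the strain
#' table as `strain_table.tsv`, the (possibly stripped) annotations as
#' `go_annotations.tsv`, and the planted truth (signatures, hidden pairs) as
#' TSVs under `dir/truth/`.
#'
#' @param lib A `sim_library`.
#' @param dir Output directory (created if absent).
#' @param format Spectrum file format, `"tsv"` or `"mzml"`.
#' @return `dir`, invisibly.
#' @export
write_sim_library <- function(lib, dir, format = c("tsv", "mzml")) {
  format <- match.arg(format)
  stopifnot(inherits(lib, "sim_library"))
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tsv") "tsv" else "mzML"
  for (s in lib$spectra) {
    write_spectrum(s, file.path(dir, "spectra",
                                paste0(attr(s, "spectrum_id"), ".", ext)),
                   format = format)
  }
  readr::write_tsv(lib$strain_table, file.path(dir, "strain_table.tsv"))
  readr::write_tsv(lib$truth_annotations$pairs,
                   file.path(dir, "go_annotations.tsv"), col_names = FALSE)
  sig <- tibble::tibble(
    go_accession = rep(names(lib$planted_signatures),
                       lengths(lib$planted_signatures)),
    bin_index = unlist(lib$planted_signatures, use.names = FALSE)
  )
  readr::write_tsv(sig, file.path(dir, "truth", "planted_signatures.tsv"))
  if (!is.null(lib$hidden_truth)) {
    readr::write_tsv(lib$hidden_truth, file.path(dir, "truth",
                                                 "hidden_annotations.tsv"))
  }
  invisible(dir)
}
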