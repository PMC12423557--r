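#' Replicate accounting of a spectral knockout library
#'
#' Summarizes a replicate-breakdown table (how many knockouts were measured
#' once, in duplicate, and so on) into total knockout and spectrum counts and
#' the coverage of the full strain collection. The published accounting of
#' the yeast knockout MALDI-TOF screen ships as
#' `system.file("extdata", "yeast_library_accounting.tsv", package =
#' "maldigo")`: 1,254 single-spectrum and 1,910 duplicate-spectrum knockouts
#' plus an independently re-measured reproducibility panel.
#'
#' @param breakdown Data frame with columns `n_knockouts` and
#'   `replicates_each`, one row per replicate class.
#' @param library_size Total number of strains in the knockout collection
#'   (default 4,847, the full yeast single-gene deletion library).
#' @return One-row tibble: `n_knockouts`, `n_spectra`, `library_size`,
#'   `coverage_pct`.
#' @export
library_accounting <- function(breakdown, library_size = 4847) {
  breakdown <- tibble::as_tibble(breakdown)
  stopifnot(all(c("n_knockouts", "replicates_each") %in% names(breakdown)),
            library_size > 0)
  n_ko <- as.integer(sum(breakdown$n_knockouts))
  tibble::tibble(
    n_knockouts = n_ko,
    n_spectra = as.integer(sum(breakdown$n_knockouts *
                                 breakdown$replicates_each)),
    library_size = as.integer(library_size),
    coverage_pct = 100 * n_ko / library_size
  )
}

#' Positive matching ratio of a GO accession
#'
#' Fraction of all fingerprint vectors annotated positive for an accession.
#'
#' @param n_positive Positive vector count(s).
#' @param n_total Total vector count (default 5,356, the size of the
#'   published fingerprint dataset).
#' @return Numeric ratio(s).
#' @export
positive_matching_ratio <- function(n_positive, n_total = 5356) {
  stopifnot(all(n_positive >= 0), n_total > 0, all(n_positive <= n_total))
  n_positive / n_total
}

#' Knockout coverage of GO accessions against a reference gene list
#'
#' For each accession, the matched-knockout coverage (percent of the
#' accession's reference genes whose knockouts were matched) and the
#' positive matching ratio of its vectors. The worked example table of three
#' accessions spanning small to very large terms ships as
#' `system.file("extdata", "go_term_examples.tsv", package = "maldigo")`.
#'
#' @param examples Data frame with columns `go_accession`,
#'   `n_positive_vectors`, `n_matched_knockouts`, `n_amigo_genes`.
#' @param n_total_vectors Total fingerprint vectors (default 5,356).
#' @return The input tibble with `matching_ratio` and `coverage_pct` added.
#' @export
go_coverage <- function(examples, n_total_vectors = 5356) {
  examples <- tibble::as_tibble(examples)
  stopifnot(all(c("go_accession", "n_positive_vectors",
                  "n_matched_knockouts", "n_amigo_genes") %in%
                  names(examples)))
  examples |>
    dplyr::mutate(
      matching_ratio = positive_matching_ratio(.data$n_positive_vectors,
                                               n_total_vectors),
      coverage_pct = 100 * .data$n_matched_knockouts / .data$n_amigo_genes
    )
}
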