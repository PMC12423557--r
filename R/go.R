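#' Gene-to-GO annotation table
#'
#' A many-to-many map from gene ids to GO accessions (`GO:` followed by seven
#' digits). Duplicate pairs are removed with a warning; malformed accessions
#' are an error.
#'
#' @param pairs Data frame with columns `gene_id` and `go_accession`.
#' @return A `go_table`: list with `pairs` (deduplicated tibble) and
#'   `genes_by_go` (named list GO -> gene ids).
#' @export
go_table <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)[, c("gene_id", "go_accession")]
  bad <- !grepl("^GO:\\d{7}$", pairs$go_accession)
  if (any(bad)) {
    stop("malformed GO accession(s): ",
         paste(utils::head(unique(pairs$go_accession[bad]), 5), collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(pairs)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene/GO pair(s) removed", call. = FALSE)
    pairs <- pairs[!dup, ]
  }
  structure(
    list(pairs = pairs,
         genes_by_go = split(pairs$gene_id, pairs$go_accession)),
    class = "go_table"
  )
}

#' @export
print.go_table <- function(x, ...) {
  cat(sprintf("<go_table> %d gene/GO pairs; %d genes; %d accessions\n",
              nrow(x$pairs), length(unique(x$pairs$gene_id)),
              length(x$genes_by_go)))
  invisible(x)
}

#' Read GO annotations from GAF 2.x or a two-column TSV
#'
#' For GAF input, rows whose qualifier contains `NOT` are dropped (with a
#' logged count); the gene identifier comes from column 2 (DB Object ID) or
#' column 3 (DB Object Symbol), the accession from column 5.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` (columns `gene_id`, `go_accession`, no header) or
#'   `"gaf"`; the default guesses from the extension and a `!gaf-version`
#'   header line.
#' @param gaf_gene_column `"id"` (column 2) or `"symbol"` (column 3).
#' @return A [go_table()].
#' @export
read_go <- function(path, format = c("auto", "tsv", "gaf"),
                    gaf_gene_column = c("id", "symbol")) {
  format <- match.arg(format)
  gaf_gene_column <- match.arg(gaf_gene_column)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("\\.gaf(\\.|$)", path) ||
                  grepl("^!gaf-version", first)) "gaf" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("expected two columns (gene_id, go_accession)",
                             call. = FALSE)
    go_table(tibble::tibble(gene_id = as.character(tab[[1]]),
                            go_accession = as.character(tab[[2]])))
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "!")]
    if (length(body) == 0L) stop("no annotation rows in ", path, call. = FALSE)
    fields <- strsplit(body, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 5L)
    if (length(short) > 0L) {
      stop("malformed GAF row at line ",
           which(!startsWith(lines, "!"))[short[1]], call. = FALSE)
    }
    qualifier <- vapply(fields, `[[`, "", 4L)
    keep <- !grepl("(^|\\|)NOT(\\||$)", qualifier)
    if (any(!keep)) {
      message(sum(!keep), " NOT-qualified GAF row(s) dropped")
    }
    col <- if (gaf_gene_column == "id") 2L else 3L
    acc <- vapply(fields, `[[`, "", 5L)[keep]
    bad <- !grepl("^GO:\\d{7}$", acc)
    if (any(bad)) {
      stop("malformed GO accession at GAF line ",
           which(!startsWith(lines, "!"))[keep][which(bad)[1]], call. = FALSE)
    }
    go_table(tibble::tibble(gene_id = vapply(fields, `[[`, "", col)[keep],
                            go_accession = acc))
  }
}

#' Per-accession positive/negative label split
#'
#' For each GO accession, positives are the fingerprint vectors of genes
#' annotated to it, negatives all other vectors of known genes. Vectors of
#' genes flagged unknown belong to neither class and never enter training.
#'
#' @param go A [go_table()].
#' @param fp A [fingerprint_set()].
#' @param unknown_genes Character vector of gene ids to exclude entirely.
#' @return Tibble with columns `go_accession`, `n_positive`, `n_negative`,
#'   and a list-column `positive` of logical masks over the rows of
#'   `fp$bits` (`NA` marks excluded unknown vectors).
#' @export
label_vectors <- function(go, fp, unknown_genes = character(0)) {
  stopifnot(inherits(go, "go_table"), inherits(fp, "fingerprint_set"))
  known <- !fp$meta$gene_id %in% unknown_genes & fp$meta$gene_id != "UNKNOWN"
  accs <- names(go$genes_by_go)
  masks <- lapply(accs, function(a) {
    pos <- fp$meta$gene_id %in% go$genes_by_go[[a]] & known
    pos[!known] <- NA
    pos
  })
  tibble::tibble(
    go_accession = accs,
    n_positive = vapply(masks, function(m) sum(m, na.rm = TRUE), 1L),
    n_negative = vapply(masks, function(m) sum(!m, na.rm = TRUE), 1L),
    positive = masks
  )
}
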