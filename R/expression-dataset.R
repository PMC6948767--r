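#' Labeled expression dataset
#'
#' An `expression_dataset` bundles one genes x samples matrix of log2-scale
#' expression values with a sample sheet assigning each sample to a condition
#' group. It is the unit of a compendium: every analysis stage
#' ([assess_query_consistency()], [profile_neighbors()], [mutual_rank()])
#' consumes one of these.
#'
#' @param values Numeric matrix, rows = genes, columns = samples. Row and
#'   column names are taken as gene and sample identifiers if `gene_ids` /
#'   `sample_ids` are not supplied. `NA` cells are permitted (treated as
#'   missing downstream via pairwise-complete correlation) but the generator
#'   never produces them.
#' @param samples Data frame with columns `sample_id` and `condition`; row
#'   order defines the authoritative sample order.
#' @param dataset_id Single string identifying the dataset.
#' @param gene_ids,sample_ids Optional character vectors overriding the
#'   matrix dimnames. Gene identifiers are opaque, case-sensitive strings; no
#'   symbol or alias resolution is performed.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `dataset_id`, `values` (named matrix) and `samples` (tibble).
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' sheet <- data.frame(sample_id = paste0("s", 1:4), condition = rep(c("a", "b"), 2))
#' ds <- expression_dataset(m, sheet, "toy")
#' dim(ds$values)
#' @export
expression_dataset <- function(values, samples, dataset_id,
                               gene_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_config("`values` must be a numeric matrix (genes x samples)")
  }
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_config("`values` must carry gene row names and sample column names")
  }
  if (!is.character(dataset_id) || length(dataset_id) != 1L || is.na(dataset_id)) {
    abort_config("`dataset_id` must be a single string")
  }
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "condition") %in% names(samples))) {
    abort_config("sample sheet must have columns `sample_id` and `condition`")
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$condition <- as.character(samples$condition)

  gid <- rownames(values)
  if (anyDuplicated(gid)) {
    abort_parse(paste0("duplicated gene id: ",
                       paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort_parse("duplicated sample id in sample sheet")
  }
  if (!identical(sort(colnames(values)), sort(samples$sample_id))) {
    abort_parse("sample sheet and matrix disagree on sample ids")
  }
  # sample sheet row order is the authority
  values <- values[, samples$sample_id, drop = FALSE]
  structure(
    list(dataset_id = dataset_id, values = values, samples = samples),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset '%s'>: %d genes x %d samples, %d condition(s)\n",
    x$dataset_id, nrow(x$values), ncol(x$values),
    dplyr::n_distinct(x$samples$condition)
  ))
  invisible(x)
}

#' @rdname expression_dataset
#' @param x An `expression_dataset`.
#' @param ... Unused.
#' @method tidy expression_dataset
#' @export
tidy.expression_dataset <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "value") |>
    dplyr::left_join(x$samples, by = "sample_id") |>
    dplyr::mutate(dataset_id = x$dataset_id, .before = 1L)
}

condition_of_samples <- function(ds) {
  stats::setNames(ds$samples$condition, ds$samples$sample_id)
}

#' Read and write expression datasets as TSV
#'
#' The on-disk dialect is two tab-delimited UTF-8 files: an expression matrix
#' whose first column header is `gene_id` and whose remaining headers are
#' sample ids (`NA` encodes a missing value), and a sample sheet with columns
#' `sample_id` and `condition` whose row order is the sample-order authority.
#' Values survive a write/read round trip at 9 significant digits.
#'
#' @param ds An [expression_dataset()].
#' @param matrix_path,samples_path Paths for the matrix and sample sheet TSVs.
#' @param dataset_id Dataset identifier attached on read.
#' @return `write_dataset()` returns the paths invisibly; `read_dataset()`
#'   returns an [expression_dataset()].
#' @examples
#' m <- matrix(1:6 / 7, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' sheet <- data.frame(sample_id = c("s1", "s2", "s3"), condition = c("a", "a", "b"))
#' ds <- expression_dataset(m, sheet, "toy")
#' tmp <- tempfile(); dir.create(tmp)
#' paths <- write_dataset(ds, file.path(tmp, "m.tsv"), file.path(tmp, "s.tsv"))
#' ds2 <- read_dataset(file.path(tmp, "m.tsv"), file.path(tmp, "s.tsv"), "toy")
#' all.equal(ds$values, ds2$values)
#' @export
write_dataset <- function(ds, matrix_path, samples_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  mat <- tibble::as_tibble(
    apply(ds$values, 2, function(v) format_sig9(v), simplify = FALSE)
  )
  mat <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(ds$values)), mat)
  readr::write_tsv(mat, matrix_path, na = "NA", progress = FALSE)
  readr::write_tsv(ds$samples, samples_path, progress = FALSE)
  invisible(c(matrix = matrix_path, samples = samples_path))
}

format_sig9 <- function(v) {
  out <- formatC(v, digits = 9L, format = "g")
  out[is.na(v)] <- NA_character_
  out
}

#' @rdname write_dataset
#' @export
read_dataset <- function(matrix_path, samples_path, dataset_id) {
  mat_tbl <- readr::read_tsv(matrix_path, na = "NA", progress = FALSE,
                             show_col_types = FALSE,
                             col_types = readr::cols(gene_id = readr::col_character(),
                                                     .default = readr::col_double()))
  if (names(mat_tbl)[1] != "gene_id") {
    abort_parse(sprintf("%s: first column header must be 'gene_id' (line 1)", matrix_path))
  }
  dup <- mat_tbl$gene_id[duplicated(mat_tbl$gene_id)]
  if (length(dup)) {
    line <- which(duplicated(mat_tbl$gene_id))[1] + 1L
    abort_parse(sprintf("%s: duplicated gene id '%s' (line %d)", matrix_path, dup[1], line))
  }
  sheet <- readr::read_tsv(samples_path, progress = FALSE, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample_id", "condition") %in% names(sheet))) {
    abort_parse(sprintf("%s: sample sheet needs columns sample_id, condition (line 1)",
                        samples_path))
  }
  unknown <- setdiff(sheet$sample_id, names(mat_tbl)[-1])
  if (length(unknown)) {
    line <- which(sheet$sample_id == unknown[1])[1] + 1L
    abort_parse(sprintf("%s: unknown sample '%s' (line %d)", samples_path, unknown[1], line))
  }
  missing <- setdiff(names(mat_tbl)[-1], sheet$sample_id)
  if (length(missing)) {
    abort_parse(sprintf("%s: matrix sample '%s' absent from sample sheet",
                        matrix_path, missing[1]))
  }
  values <- as.matrix(mat_tbl[, -1, drop = FALSE])
  rownames(values) <- mat_tbl$gene_id
  expression_dataset(values, sheet, dataset_id)
}

#' Read and write GMT gene-set annotation files
#'
#' Standard GMT: one term per line, `term_id TAB description TAB gene TAB
#' gene ...`. Reading is delegated to [fgsea::gmtPathways()]; descriptions are
#' not round-tripped by that reader, so `read_gmt()` re-parses them from the
#' file.
#'
#' @param annotation Named list of character vectors (term id -> gene set).
#' @param path File path.
#' @param descriptions Optional named character vector of term descriptions;
#'   defaults to the term id.
#' @return `read_gmt()` returns a named list of character gene vectors with a
#'   `descriptions` attribute; `write_gmt()` returns `path` invisibly.
#' @export
write_gmt <- function(annotation, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(annotation), names(annotation))
  }
  lines <- vapply(names(annotation), function(term) {
    paste(c(term, descriptions[[term]], annotation[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  fields <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  desc <- stats::setNames(
    vapply(fields, function(f) if (length(f) >= 2) f[2] else "", character(1)),
    vapply(fields, `[`, character(1), 1)
  )
  attr(sets, "descriptions") <- desc[names(sets)]
  sets
}
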