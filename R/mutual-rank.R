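#' Mutual-rank coexpression table for a query gene
#'
#' For every gene B, computes the rank of B in the query's correlation-sorted
#' neighbor list (`rank_query_to_gene`) and the rank of the query in B's list
#' (`rank_gene_to_query`); the mutual rank is the geometric mean
#' `sqrt(r1 * r2)`. Low mutual rank means strong *reciprocal* coexpression —
#' the convention of precomputed coexpression databases — and is the
#' independent validation axis for a consensus gene list. Lists rank by
#' signed Pearson correlation descending, ties broken by gene id ascending.
#'
#' The full gene-by-gene correlation matrix is materialised, so the genome
#' size is guarded by `max_genes`.
#'
#' @inheritParams assess_query_consistency
#' @param k Size of `top_set` (first `k` genes by mutual rank ascending).
#' @param max_genes Resource guard on the dataset's gene count, default 6000.
#' @return A `mutual_rank_table`: tibble `gene_id`, `rank_query_to_gene`,
#'   `rank_gene_to_query`, `mutual_rank`, sorted by `mutual_rank` ascending
#'   then `gene_id`; attributes `query_gene` and `top_set` (character vector
#'   of length <= `k`).
#' @examples
#' cmp <- generate_compendium(compendium_config(n_genes = 40, module_size = 4, seed = 5))
#' mr <- mutual_rank(cmp$datasets[[1]], "GQRY", k = 5)
#' attr(mr, "top_set")
#' @export
mutual_rank <- function(ds, query_gene, k = 200, max_genes = 6000) {
  stopifnot(inherits(ds, "expression_dataset"))
  genes <- rownames(ds$values)
  if (length(genes) > max_genes) {
    abort_config(sprintf("dataset has %d genes, above the max_genes guard (%d)",
                         length(genes), max_genes))
  }
  q <- query_row(ds, query_gene)
  if (sum(!is.na(q)) < 3L || stats::var(q, na.rm = TRUE) == 0) {
    abort_compute(sprintf("query gene '%s' has zero variance or < 3 values",
                          query_gene))
  }
  r <- suppressWarnings(
    stats::cor(t(ds$values), use = "pairwise.complete.obs")
  )
  n <- nrow(r)
  # rank_mat[a, b] = rank of gene b in gene a's signed-descending list
  rank_mat <- matrix(NA_integer_, n, n, dimnames = dimnames(r))
  for (a in seq_len(n)) {
    v <- r[a, ]
    v[a] <- NA
    idx <- which(!is.na(v))
    ord <- idx[order(-v[idx], genes[idx])]
    rank_mat[a, ord] <- seq_along(ord)
  }
  qi <- match(query_gene, genes)
  others <- setdiff(seq_len(n), qi)
  r1 <- rank_mat[qi, others]
  r2 <- rank_mat[others, qi]
  ok <- !is.na(r1) & !is.na(r2)
  out <- tibble::tibble(
    gene_id = genes[others][ok],
    rank_query_to_gene = as.integer(r1[ok]),
    rank_gene_to_query = as.integer(r2[ok]),
    mutual_rank = sqrt(as.double(r1[ok]) * as.double(r2[ok]))
  ) |>
    dplyr::arrange(.data$mutual_rank, .data$gene_id)
  attr(out, "query_gene") <- query_gene
  attr(out, "top_set") <- utils::head(out$gene_id, k)
  class(out) <- c("mutual_rank_table", class(out))
  out
}

#' Pool the condition groups of several datasets into one validation dataset
#'
#' Concatenates the sample columns of datasets sharing a gene universe; used
#' to build the held-out compendium on which [mutual_rank()] validates a
#' consensus list.
#'
#' @param datasets List of [expression_dataset()] with identical gene ids.
#' @param dataset_id Id for the pooled dataset.
#' @return An [expression_dataset()].
#' @export
pool_datasets <- function(datasets, dataset_id = "pooled") {
  stopifnot(length(datasets) >= 1)
  genes <- rownames(datasets[[1]]$values)
  for (ds in datasets[-1]) {
    if (!identical(rownames(ds$values), genes)) {
      abort_input("datasets must share an identical gene universe to be pooled")
    }
  }
  values <- do.call(cbind, lapply(datasets, function(d) d$values))
  samples <- purrr::list_rbind(purrr::map(datasets, function(d) {
    dplyr::mutate(d$samples,
                  sample_id = paste(d$dataset_id, .data$sample_id, sep = "."),
                  condition = paste(d$dataset_id, .data$condition, sep = "."))
  }))
  colnames(values) <- samples$sample_id
  expression_dataset(values, samples, dataset_id)
}

#' Hypergeometric significance of a gene-set overlap
#'
#' One-sided probability of observing at least the given overlap between two
#' gene sets drawn from a common universe: `P(X >= |A intersect B|)` for
#' `X ~ Hypergeometric(|universe|, |A|, |B|)`.
#'
#' @param set_a,set_b Character vectors of gene ids; must be subsets of
#'   `universe`.
#' @param universe Character vector, the background gene universe.
#' @return One-row tibble: `set_a_size`, `set_b_size`, `overlap_count`,
#'   `universe_size`, `hypergeometric_p`.
#' @examples
#' overlap_significance(c("a", "b"), c("b", "c"), letters[1:10])
#' @export
overlap_significance <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    abort_input("both sets must be contained in the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), length(universe) - length(set_a),
                     length(set_b), lower.tail = FALSE)
  tibble::tibble(
    set_a_size = length(set_a),
    set_b_size = length(set_b),
    overlap_count = k,
    universe_size = length(universe),
    hypergeometric_p = p
  )
}
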