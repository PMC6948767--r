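#' Count neighbor membership across datasets
#'
#' The consensus score of a gene is the simple count of datasets in which it
#' appears among the query's top-K profile neighbors. Genes never appearing
#' are omitted (implicit count 0).
#'
#' @param profiles List of neighbor-profile tibbles from
#'   [profile_neighbors()] (or any tibbles with `dataset_id`, `query_gene`,
#'   `gene_id` columns, e.g. read from replay sheets). All must share one
#'   query gene and have distinct dataset ids.
#' @return A `consensus_table`: tibble with columns `gene_id`, `count`,
#'   sorted by count descending then gene id ascending; attributes
#'   `query_gene` and `dataset_ids`.
#' @examples
#' p1 <- tibble::tibble(dataset_id = "d1", query_gene = "q", gene_id = c("a", "b"))
#' p2 <- tibble::tibble(dataset_id = "d2", query_gene = "q", gene_id = c("b", "c"))
#' count_neighbors(list(p1, p2))
#' @export
count_neighbors <- function(profiles) {
  if (!length(profiles)) abort_input("`profiles` must hold at least one profile")
  all <- purrr::list_rbind(purrr::map(profiles, function(p) {
    tibble::as_tibble(p)[, c("dataset_id", "query_gene", "gene_id")]
  }))
  queries <- unique(all$query_gene)
  if (length(queries) != 1L) {
    abort_input(sprintf("profiles mix query genes: %s",
                        paste(queries, collapse = ", ")))
  }
  ids <- purrr::map_chr(profiles, function(p) unique(p$dataset_id)[1])
  if (anyDuplicated(ids)) {
    abort_input(sprintf("duplicate dataset_id among profiles: %s",
                        ids[duplicated(ids)][1]))
  }
  if (queries %in% all$gene_id) {
    abort_input("a profile lists the query gene as its own neighbor")
  }
  counts <- all |>
    dplyr::distinct(.data$dataset_id, .data$gene_id) |>
    dplyr::count(.data$gene_id, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$gene_id)
  attr(counts, "query_gene") <- queries
  attr(counts, "dataset_ids") <- ids
  class(counts) <- c("consensus_table", class(counts))
  counts
}

#' Extract the consensus gene set at a minimum dataset count
#'
#' Genes appearing among the query's top-K neighbors in at least `min_count`
#' datasets, ordered by count descending then gene id ascending. The default
#' `min_count = 4` encodes the "more than 3 datasets" rule.
#'
#' @param table A `consensus_table` from [count_neighbors()].
#' @param min_count Minimum number of datasets (inclusive), between 1 and the
#'   number of datasets counted.
#' @return Character vector of gene ids (possibly empty).
#' @export
consensus_set <- function(table, min_count = 4) {
  n_ds <- length(attr(table, "dataset_ids"))
  if (min_count < 1 || min_count > n_ds) {
    abort_config(sprintf("`min_count` must lie in [1, %d]", n_ds))
  }
  table |>
    dplyr::filter(.data$count >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$gene_id) |>
    dplyr::pull("gene_id")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("<consensus_table> query '%s' over %d dataset(s)\n",
              attr(x, "query_gene"), length(attr(x, "dataset_ids"))))
  NextMethod()
}

#' @rdname count_neighbors
#' @param x A `consensus_table`.
#' @param object A `consensus_table`.
#' @param min_count Threshold used for the `in_consensus` flag / summary.
#' @param ... Unused.
#' @method tidy consensus_table
#' @export
tidy.consensus_table <- function(x, min_count = 4, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(in_consensus = .data$count >= min_count)
}

#' @rdname count_neighbors
#' @method glance consensus_table
#' @export
glance.consensus_table <- function(x, min_count = 4, ...) {
  tibble::tibble(
    query_gene = attr(x, "query_gene"),
    n_datasets = length(attr(x, "dataset_ids")),
    n_genes_counted = nrow(x),
    min_count = min_count,
    consensus_size = sum(x$count >= min_count)
  )
}

#' @rdname count_neighbors
#' @method autoplot consensus_table
#' @export
autoplot.consensus_table <- function(object, min_count = 4, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::count(.data$count, name = "n_genes")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$count), y = .data$n_genes)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = match(min_count, sort(unique(df$count))) - 0.5,
                        linetype = 2, na.rm = TRUE) +
    ggplot2::labs(x = "datasets in which gene is a top-K neighbor",
                  y = "genes") +
    ggplot2::theme_minimal()
}
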