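#' Fisher's exact overrepresentation of a gene list in annotation terms
#'
#' For each term, forms the 2x2 table of list membership against term
#' membership within a declared background universe and computes the
#' one-sided (enrichment) Fisher exact p — the upper hypergeometric tail
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `k` is the overlap,
#' `n` the list size, `K` the term size and `N` the background size. Term
#' gene sets are intersected with the background before testing; a list gene
#' absent from the background is a hard error (the comparison is against a
#' declared reference universe, not a convenience subset).
#'
#' @param gene_list Character vector of genes (the foreground list).
#' @param annotation Named list of character vectors (term id -> gene set),
#'   e.g. from [read_gmt()] or [generate_annotation()].
#' @param background Character vector, the reference universe.
#' @return Tibble with one row per term: `term_id`, `term_name`, `k`, `n`,
#'   `K`, `N`, `fold_enrichment` (`(k/n)/(K/N)`, `NA` when `K = 0`),
#'   `p_value`, `q_value` (Benjamini-Hochberg over the returned terms).
#' @examples
#' ann <- list(t1 = c("a", "b", "c"), t2 = c("d", "e"))
#' fisher_overrepresentation(c("a", "b"), ann, letters[1:10])
#' @export
fisher_overrepresentation <- function(gene_list, annotation, background) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  if (!length(gene_list)) abort_input("`gene_list` is empty")
  if (!length(background)) abort_input("`background` is empty")
  stray <- setdiff(gene_list, background)
  if (length(stray)) {
    abort_input(sprintf("%d list gene(s) absent from the background (e.g. '%s')",
                        length(stray), stray[1]))
  }
  if (!length(annotation)) abort_input("`annotation` holds no terms")
  desc <- attr(annotation, "descriptions")
  n <- length(gene_list)
  N <- length(background)
  rows <- purrr::imap(annotation, function(genes, term) {
    term_bg <- intersect(unique(genes), background)
    K <- length(term_bg)
    k <- length(intersect(gene_list, term_bg))
    tibble::tibble(
      term_id = term,
      term_name = if (!is.null(desc) && !is.na(desc[term])) unname(desc[term]) else term,
      k = k, n = n, K = K, N = N,
      fold_enrichment = if (K > 0) (k / n) / (K / N) else NA_real_,
      p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  })
  out <- purrr::list_rbind(rows)
  out$q_value <- bh_fdr(out$p_value)
  out
}

#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' Standard BH: sort the m p-values ascending, compute `p_(i) * m / i`, and
#' enforce monotonicity by a cumulative minimum from the largest p down; the
#' result is mapped back to the input order, so it is invariant to input
#' permutation.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort_input("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Filter an enrichment table at an FDR cutoff
#'
#' @param rows Tibble from [fisher_overrepresentation()] (must carry
#'   `q_value`).
#' @param fdr_cutoff Keep rows with `q_value < fdr_cutoff`; default 0.05.
#' @return The filtered tibble, sorted by `q_value` ascending then
#'   `term_id`; possibly empty.
#' @export
enrichment_report <- function(rows, fdr_cutoff = 0.05) {
  if (!"q_value" %in% names(rows)) abort_input("`rows` must carry a q_value column")
  rows |>
    dplyr::filter(.data$q_value < fdr_cutoff) |>
    dplyr::arrange(.data$q_value, .data$term_id)
}

#' Dot plot of an enrichment table
#'
#' Fold enrichment against terms, coloured by -log10 q, for rows passing the
#' cutoff (all rows if none pass).
#'
#' @param object Tibble from [fisher_overrepresentation()].
#' @param fdr_cutoff Cutoff used to select the rows drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(object, fdr_cutoff = 0.05, ...) {
  shown <- enrichment_report(object, fdr_cutoff)
  if (!nrow(shown)) shown <- dplyr::arrange(object, .data$q_value)
  shown <- dplyr::mutate(shown,
                         term_id = stats::reorder(.data$term_id,
                                                  .data$fold_enrichment))
  ggplot2::ggplot(shown,
                  ggplot2::aes(x = .data$fold_enrichment, y = .data$term_id,
                               size = .data$k,
                               colour = -log10(.data$q_value))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "overlap",
                  colour = expression(-log[10] ~ q)) +
    ggplot2::theme_minimal()
}
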