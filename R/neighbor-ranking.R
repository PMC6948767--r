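#' Quantify dataset consistency of the query gene
#'
#' Screens one dataset for a reproducible condition effect on the query gene,
#' replacing by-eye curation of repository profile queries with a fixed rule:
#' a one-way ANOVA of the query row across condition groups, summarised by
#' eta-squared (`SS_between / SS_total`, the fraction of query variance
#' explained by condition) and the ANOVA F test. A dataset is retained when
#' `eta_squared >= eta_threshold` **and** `p_value < alpha` — i.e. the query
#' is stable within conditions and differs between them. A query row with
#' zero total variance gives `eta_squared = 0`, `NA` F/p, and is not
#' retained.
#'
#' @param ds An [expression_dataset()].
#' @param query_gene Gene identifier; must be a row of `ds`.
#' @param eta_threshold Minimum eta-squared, default 0.5.
#' @param alpha Significance level for the ANOVA p-value, default 0.05.
#' @return One-row tibble: `dataset_id`, `eta_squared`, `f_statistic`,
#'   `p_value`, `retained`.
#' @examples
#' m <- rbind(GQ = c(1, 2, 5, 6), G2 = rnorm(4))
#' sheet <- data.frame(sample_id = paste0("s", 1:4), condition = c("A", "A", "B", "B"))
#' colnames(m) <- sheet$sample_id
#' assess_query_consistency(expression_dataset(m, sheet, "toy"), "GQ")
#' @export
assess_query_consistency <- function(ds, query_gene,
                                     eta_threshold = 0.5, alpha = 0.05) {
  stopifnot(inherits(ds, "expression_dataset"))
  y <- query_row(ds, query_gene)
  g <- ds$samples$condition
  keep <- !is.na(y)
  y <- y[keep]
  g <- g[keep]
  usable <- names(which(table(g) >= 2L))
  if (length(usable) < 2L) {
    abort_structural(sprintf(
      "dataset '%s': need >= 2 conditions with >= 2 non-missing query samples",
      ds$dataset_id))
  }
  in_use <- g %in% usable
  y <- y[in_use]
  g <- factor(g[in_use])

  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) {
    return(tibble::tibble(dataset_id = ds$dataset_id, eta_squared = 0,
                          f_statistic = NA_real_, p_value = NA_real_,
                          retained = FALSE))
  }
  fit <- stats::anova(stats::lm(y ~ g))
  ss_between <- fit$`Sum Sq`[1]
  eta2 <- ss_between / ss_total
  f <- fit$`F value`[1]
  p <- fit$`Pr(>F)`[1]
  tibble::tibble(
    dataset_id = ds$dataset_id,
    eta_squared = eta2,
    f_statistic = f,
    p_value = p,
    retained = !is.na(p) && eta2 >= eta_threshold && p < alpha
  )
}

query_row <- function(ds, query_gene) {
  if (!query_gene %in% rownames(ds$values)) {
    abort_lookup(sprintf("query gene '%s' not found in dataset '%s'",
                         query_gene, ds$dataset_id))
  }
  ds$values[query_gene, ]
}

#' Filter a compendium by query-gene consistency
#'
#' Applies [assess_query_consistency()] to every dataset and binds the
#' reports.
#'
#' @inheritParams assess_query_consistency
#' @param datasets List of [expression_dataset()] objects.
#' @return Tibble with one row per dataset (columns as in
#'   [assess_query_consistency()]).
#' @export
filter_compendium <- function(datasets, query_gene,
                              eta_threshold = 0.5, alpha = 0.05) {
  purrr::map(datasets, assess_query_consistency, query_gene = query_gene,
             eta_threshold = eta_threshold, alpha = alpha) |>
    purrr::list_rbind()
}

#' Top-K correlation profile neighbors of a query gene
#'
#' Computes, within one dataset, the correlation between the query gene's
#' expression profile and every other gene over pairwise-complete samples,
#' and returns the `k` most positively correlated genes — the query's
#' "profile neighbors". Ranking is by signed correlation descending (a
#' strongly anti-correlated gene is *not* a neighbor); ties are broken by
#' gene id, ascending, so output is deterministic. Genes with fewer than 3
#' complete sample pairs against the query, or zero variance on those pairs,
#' are excluded and listed in the `skipped` attribute.
#'
#' @inheritParams assess_query_consistency
#' @param k Number of neighbors to retain (fewer if fewer genes qualify).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble with columns `dataset_id`, `query_gene`, `gene_id`, `r`,
#'   `rank` (1..nrow), plus attributes `k_requested`, `genes_evaluated` and
#'   `skipped` (tibble `gene_id`, `reason`).
#' @examples
#' cmp <- generate_compendium(compendium_config(n_genes = 50, module_size = 5, seed = 2))
#' profile_neighbors(cmp$datasets[[1]], "GQRY", k = 10)
#' @export
profile_neighbors <- function(ds, query_gene, k = 200,
                              method = c("pearson", "spearman")) {
  stopifnot(inherits(ds, "expression_dataset"))
  method <- match.arg(method)
  if (k < 1) abort_config("`k` must be >= 1")
  q <- query_row(ds, query_gene)
  others <- ds$values[setdiff(rownames(ds$values), query_gene), , drop = FALSE]
  if (!nrow(others)) abort_input("dataset holds no gene other than the query")

  q_ok <- !is.na(q)
  complete_pairs <- as.vector((!is.na(others)) %*% q_ok)
  # variance over the pairwise-complete samples of each gene
  masked <- others
  masked[, !q_ok] <- NA
  pair_var <- apply(masked, 1L, function(v) stats::var(v[!is.na(v)]))
  pair_var[is.na(pair_var)] <- 0
  eligible <- complete_pairs >= 3L & pair_var > 0

  skipped <- tibble::tibble(
    gene_id = rownames(others)[!eligible],
    reason = ifelse(complete_pairs[!eligible] < 3L, "lt3_complete_pairs",
                    "zero_variance")
  )
  if (!any(eligible)) {
    abort_compute(sprintf(
      "dataset '%s': every gene was skipped; no neighbor profile", ds$dataset_id))
  }
  r <- suppressWarnings(
    stats::cor(t(others[eligible, , drop = FALSE]), q,
               use = "pairwise.complete.obs", method = method)[, 1]
  )
  ord <- order(-r, names(r))
  top <- utils::head(ord, k)
  out <- tibble::tibble(
    dataset_id = ds$dataset_id,
    query_gene = query_gene,
    gene_id = names(r)[top],
    r = unname(r[top]),
    rank = seq_along(top)
  )
  attr(out, "k_requested") <- as.integer(k)
  attr(out, "genes_evaluated") <- sum(eligible)
  attr(out, "skipped") <- skipped
  out
}

#' Plot a dataset filter report
#'
#' Eta-squared against -log10 ANOVA p per dataset, with the retention
#' thresholds drawn as reference lines.
#'
#' @param report Tibble from [filter_compendium()].
#' @param eta_threshold,alpha Thresholds to draw; defaults match
#'   [assess_query_consistency()].
#' @return A ggplot object.
#' @export
plot_filter_report <- function(report, eta_threshold = 0.5, alpha = 0.05) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$eta_squared,
                               y = -log10(.data$p_value),
                               colour = .data$retained,
                               label = .data$dataset_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = eta_threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = expression(eta^2 ~ "(between-condition variance fraction)"),
                  y = expression(-log[10] ~ p),
                  colour = "retained") +
    ggplot2::theme_minimal()
}
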