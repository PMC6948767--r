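#' Configuration for a synthetic expression compendium
#'
#' Collects the parameters of the generative model behind
#' [generate_compendium()]: a compendium of log2-scale bulk expression
#' datasets, each with `n_conditions` condition groups, in which a query gene
#' carries a condition effect ("consistent" datasets) or none ("inconsistent"
#' decoys), plus a planted module of genes correlated with the query.
#'
#' Defaults describe a compendium typical of public repository series: 6
#' consistent and 3 decoy datasets of 2000 genes, 3 conditions with 8 samples
#' each, a 4-fold (2 log2 units) query shift per condition step, unit residual
#' noise, and a 50-gene module at target correlation 0.9.
#'
#' @param n_datasets Number of consistent datasets (query mean differs across
#'   conditions).
#' @param n_decoy_datasets Number of inconsistent decoy datasets (query mean
#'   flat across conditions).
#' @param n_genes Genome size, including the query gene.
#' @param module_size Number of planted co-regulated genes (excluding the
#'   query itself).
#' @param n_conditions Condition groups per dataset; at least 2.
#' @param samples_per_condition Samples per condition group; at least 2.
#' @param effect_size Mean query shift between successive conditions, log2
#'   units.
#' @param module_correlation Target Pearson correlation rho in (0, 1] of each
#'   module gene with the query.
#' @param noise_sd Residual standard deviation, log2 units; >= 0.
#' @param seed Integer random seed; the whole compendium is reproducible from
#'   it.
#' @return A `compendium_config` list.
#' @examples
#' cfg <- compendium_config(n_genes = 200, module_size = 10, seed = 1)
#' cfg$module_correlation
#' @export
compendium_config <- function(n_datasets = 6, n_decoy_datasets = 3,
                              n_genes = 2000, module_size = 50,
                              n_conditions = 3, samples_per_condition = 8,
                              effect_size = 2, module_correlation = 0.9,
                              noise_sd = 1, seed = 1L) {
  cfg <- list(
    n_datasets = as.integer(n_datasets),
    n_decoy_datasets = as.integer(n_decoy_datasets),
    n_genes = as.integer(n_genes),
    module_size = as.integer(module_size),
    n_conditions = as.integer(n_conditions),
    samples_per_condition = as.integer(samples_per_condition),
    effect_size = as.numeric(effect_size),
    module_correlation = as.numeric(module_correlation),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  check_pos <- function(field, min) {
    if (is.na(cfg[[field]]) || cfg[[field]] < min) {
      abort_config(sprintf("`%s` must be >= %s", field, format(min)))
    }
  }
  check_pos("n_datasets", 0L)
  check_pos("n_decoy_datasets", 0L)
  check_pos("n_genes", 2L)
  check_pos("module_size", 0L)
  check_pos("n_conditions", 2L)
  check_pos("samples_per_condition", 2L)
  check_pos("noise_sd", 0)
  if (cfg$module_size >= cfg$n_genes) {
    abort_config("`module_size` must be smaller than `n_genes`")
  }
  if (is.na(cfg$module_correlation) ||
      cfg$module_correlation <= 0 || cfg$module_correlation > 1) {
    abort_config("`module_correlation` must lie in (0, 1]")
  }
  if (is.na(cfg$seed)) abort_config("`seed` must be an integer")
  structure(cfg, class = "compendium_config")
}

#' Generate a synthetic compendium with a planted co-regulated module
#'
#' Simulates `n_datasets` consistent and `n_decoy_datasets` inconsistent
#' expression datasets over one shared gene universe. In every dataset the
#' query gene is `baseline + delta * (condition index - 1) + N(0, sigma)`
#' with `delta = effect_size` in consistent datasets and `delta = 0` in
#' decoys. Each planted module gene is built from the standardized realized
#' query profile `z`: `x = rho * z + sqrt(1 - rho^2) * eps`, `eps ~ N(0, 1)`
#' i.i.d., rescaled by `noise_sd` and shifted by a per-gene baseline — so at
#' `rho = 1` a module gene is an affine image of the query and its sample
#' correlation is exactly 1. Background genes are independent
#' `N(baseline, noise_sd)` draws with no condition effect.
#'
#' Each dataset draws from its own deterministic substream of `seed`, so
#' enlarging the compendium never perturbs earlier datasets.
#'
#' @param config A [compendium_config()].
#' @return A list with elements `datasets` (list of [expression_dataset()],
#'   consistent first, ids `DS1..` and `DECOY1..`) and `truth`, a list with
#'   `query_gene`, `module_genes`, `enriched_term_id` (filled by
#'   [generate_annotation()]), `consistent` (named logical by dataset id) and
#'   `config`.
#' @examples
#' cmp <- generate_compendium(compendium_config(n_genes = 100, module_size = 5,
#'                                              n_datasets = 2, seed = 7))
#' names(cmp$truth$consistent)
#' @export
generate_compendium <- function(config) {
  if (!inherits(config, "compendium_config")) config <- do.call(compendium_config, config)
  n_total <- config$n_datasets + config$n_decoy_datasets
  if (n_total < 1L) abort_config("`n_datasets` + `n_decoy_datasets` must be >= 1")

  query_gene <- "GQRY"
  module_genes <- if (config$module_size > 0) {
    sprintf("MOD%04d", seq_len(config$module_size))
  } else character(0)
  n_bg <- config$n_genes - config$module_size - 1L
  background <- if (n_bg > 0) sprintf("BG%05d", seq_len(n_bg)) else character(0)
  gene_ids <- c(query_gene, module_genes, background)

  ids <- c(
    if (config$n_datasets > 0) sprintf("DS%d", seq_len(config$n_datasets)),
    if (config$n_decoy_datasets > 0) sprintf("DECOY%d", seq_len(config$n_decoy_datasets))
  )
  consistent <- stats::setNames(
    c(rep(TRUE, config$n_datasets), rep(FALSE, config$n_decoy_datasets)), ids
  )

  datasets <- purrr::imap(consistent, function(is_consistent, id) {
    i <- match(id, ids)
    simulate_dataset(config, id, is_consistent,
                     substream_seed(config$seed, i),
                     gene_ids, query_gene, module_genes)
  })

  truth <- list(
    query_gene = query_gene,
    module_genes = module_genes,
    enriched_term_id = NA_character_,
    consistent = consistent,
    config = config
  )
  list(datasets = unname(datasets), truth = truth)
}

simulate_dataset <- function(config, dataset_id, is_consistent, seed,
                             gene_ids, query_gene, module_genes) {
  n_s <- config$n_conditions * config$samples_per_condition
  cond <- rep(seq_len(config$n_conditions), each = config$samples_per_condition)
  sample_ids <- sprintf("%s_s%02d", dataset_id, seq_len(n_s))
  rho <- config$module_correlation
  sd0 <- config$noise_sd

  withr::with_seed(seed, {
    baselines <- stats::rnorm(length(gene_ids), mean = 8, sd = 2)
    names(baselines) <- gene_ids
    delta <- if (is_consistent) config$effect_size else 0
    q <- baselines[[query_gene]] + delta * (cond - 1) + stats::rnorm(n_s, 0, sd0)
    values <- matrix(NA_real_, length(gene_ids), n_s,
                     dimnames = list(gene_ids, sample_ids))
    values[query_gene, ] <- q
    if (length(module_genes)) {
      z <- if (stats::sd(q) > 0) (q - mean(q)) / stats::sd(q) else q * 0
      eps <- matrix(stats::rnorm(length(module_genes) * n_s), length(module_genes), n_s)
      mod <- rho * matrix(z, length(module_genes), n_s, byrow = TRUE) +
        sqrt(1 - rho^2) * eps
      values[module_genes, ] <- sd0 * mod + baselines[module_genes]
    }
    bg <- setdiff(gene_ids, c(query_gene, module_genes))
    if (length(bg)) {
      values[bg, ] <- baselines[bg] +
        matrix(stats::rnorm(length(bg) * n_s, 0, sd0), length(bg), n_s)
    }
  })

  expression_dataset(
    values,
    tibble::tibble(sample_id = sample_ids, condition = sprintf("cond%d", cond)),
    dataset_id
  )
}

#' Generate a gene-set annotation with one designated enriched term
#'
#' Builds a GMT-style annotation over the compendium's gene universe: one
#' term (`TERM_MODULE`) is the planted module plus `n_decoy_genes` random
#' non-module genes — the designated enriched term — and the remaining
#' `n_terms - 1` terms are uniform random gene sets with sizes drawn from
#' `term_size_range`.
#'
#' @param truth The `truth` element returned by [generate_compendium()]
#'   (updated copy returned in the result).
#' @param n_terms Total number of terms, >= 1.
#' @param term_size_range Integer pair: inclusive size bounds for the random
#'   terms.
#' @param n_decoy_genes Non-module genes appended to the enriched term.
#' @param seed Integer seed.
#' @return List with `annotation` (named list term -> gene vector,
#'   serializable via [write_gmt()]) and `truth` with `enriched_term_id` set.
#' @examples
#' cmp <- generate_compendium(compendium_config(n_genes = 100, module_size = 5, seed = 3))
#' ann <- generate_annotation(cmp$truth, n_terms = 5, seed = 3)
#' ann$truth$enriched_term_id
#' @export
generate_annotation <- function(truth, n_terms = 50,
                                term_size_range = c(10L, 100L),
                                n_decoy_genes = 50, seed = 1L) {
  if (n_terms < 1) abort_config("`n_terms` must be >= 1")
  universe <- gene_universe(truth)
  if (max(term_size_range) > length(universe)) {
    abort_config("`term_size_range` exceeds the gene universe size")
  }
  module <- truth$module_genes
  non_module <- setdiff(universe, c(module, truth$query_gene))
  n_decoy_genes <- min(n_decoy_genes, length(non_module))

  annotation <- withr::with_seed(as.integer(seed), {
    enriched <- c(module, sample(non_module, n_decoy_genes))
    rest <- if (n_terms > 1) {
      sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_terms - 1L,
                      replace = TRUE)
      stats::setNames(
        lapply(sizes, function(k) sample(universe, k)),
        sprintf("TERM_RAND%03d", seq_len(n_terms - 1L))
      )
    } else list()
    c(list(TERM_MODULE = enriched), rest)
  })
  truth$enriched_term_id <- "TERM_MODULE"
  list(annotation = annotation, truth = truth)
}

gene_universe <- function(truth) {
  cfg <- truth$config
  n_bg <- cfg$n_genes - cfg$module_size - 1L
  c(truth$query_gene, truth$module_genes,
    if (n_bg > 0) sprintf("BG%05d", seq_len(n_bg)) else character(0))
}

#' Serialize the synthetic ground truth as JSON
#'
#' @param truth A truth list from [generate_compendium()] /
#'   [generate_annotation()].
#' @param path Output JSON path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns
#'   the truth list (with `config` restored as a [compendium_config()]).
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$config <- unclass(out$config)
  out$consistent <- as.list(out$consistent)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$consistent <- unlist(raw$consistent)
  raw$module_genes <- as.character(raw$module_genes)
  raw$config <- do.call(compendium_config, raw$config)
  raw
}

#' Write a whole compendium to a directory
#'
#' Lays out `<dir>/<dataset_id>.matrix.tsv` + `<dataset_id>.samples.tsv` per
#' dataset plus `truth.json`; [read_compendium()] restores it.
#'
#' @param compendium Result of [generate_compendium()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_compendium <- function(compendium, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in compendium$datasets) {
    write_dataset(ds,
                  file.path(dir, paste0(ds$dataset_id, ".matrix.tsv")),
                  file.path(dir, paste0(ds$dataset_id, ".samples.tsv")))
  }
  write_truth(compendium$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(dir) {
  mats <- sort(list.files(dir, pattern = "\\.matrix\\.tsv$", full.names = TRUE))
  if (!length(mats)) abort_input(sprintf("no *.matrix.tsv files under %s", dir))
  datasets <- lapply(mats, function(m) {
    id <- sub("\\.matrix\\.tsv$", "", basename(m))
    read_dataset(m, file.path(dir, paste0(id, ".samples.tsv")), id)
  })
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) read_truth(truth_path) else NULL
  list(datasets = datasets, truth = truth)
}
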