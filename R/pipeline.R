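#' Resolved configuration of a consensus-coexpression run
#'
#' Collects the numeric choices of the whole pipeline (top-K list size,
#' minimum dataset count, consistency-filter thresholds, FDR cutoff), the
#' query gene and the input/output paths. Defaults are `k_neighbors = 200`,
#' `consensus_min_count = 4` ("more than 3 datasets"), `eta_threshold = 0.5`,
#' `filter_alpha = 0.05`, `fdr_cutoff = 0.05`. Every run writes a manifest
#' echoing the resolved configuration and the md5 checksums of all file
#' inputs.
#'
#' @param query_gene Query gene identifier.
#' @param k_neighbors Top-K neighbor list size per dataset.
#' @param consensus_min_count Minimum number of datasets for consensus
#'   membership.
#' @param eta_threshold,filter_alpha Consistency-filter thresholds (see
#'   [assess_query_consistency()]).
#' @param fdr_cutoff Enrichment report FDR cutoff.
#' @param seed Integer seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters when the compendium is generated in the
#'   same run).
#' @param compendium_dir Directory of datasets in the [write_compendium()]
#'   layout; ignored when `datasets` are passed to [run_pipeline()] directly.
#' @param annotation_path GMT file path; ignored when `annotation` is passed
#'   directly.
#' @param validation_matrix,validation_samples Paths of the held-out
#'   validation dataset; when absent the validation compendium is the pooled
#'   input compendium (all datasets, conditions concatenated).
#' @param background Enrichment universe: `"all"` (every gene in the
#'   compendium) or `"annotated"` (only genes appearing in the annotation).
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @return A `run_config` list.
#' @export
run_config <- function(query_gene,
                       k_neighbors = 200,
                       consensus_min_count = 4,
                       eta_threshold = 0.5,
                       filter_alpha = 0.05,
                       fdr_cutoff = 0.05,
                       seed = 1L,
                       compendium_dir = NULL,
                       annotation_path = NULL,
                       validation_matrix = NULL,
                       validation_samples = NULL,
                       background = c("all", "annotated"),
                       out_dir = NULL) {
  if (missing(query_gene) || !is.character(query_gene) || length(query_gene) != 1) {
    abort_config("`query_gene` must be a single string")
  }
  if (k_neighbors < 1) abort_config("`k_neighbors` must be >= 1")
  if (consensus_min_count < 1) abort_config("`consensus_min_count` must be >= 1")
  if (fdr_cutoff <= 0 || fdr_cutoff > 1) abort_config("`fdr_cutoff` must lie in (0, 1]")
  structure(list(
    query_gene = query_gene,
    k_neighbors = as.integer(k_neighbors),
    consensus_min_count = as.integer(consensus_min_count),
    eta_threshold = as.numeric(eta_threshold),
    filter_alpha = as.numeric(filter_alpha),
    fdr_cutoff = as.numeric(fdr_cutoff),
    seed = as.integer(seed),
    compendium_dir = compendium_dir,
    annotation_path = annotation_path,
    validation_matrix = validation_matrix,
    validation_samples = validation_samples,
    background = match.arg(background),
    out_dir = out_dir
  ), class = "run_config")
}

#' Run the consensus coexpression pipeline end to end
#'
#' Orchestrates filter -> rank -> count -> validate -> enrich on a compendium:
#' consistency-filters every dataset for the query gene, computes top-K
#' profile neighbors in each retained dataset, counts neighbor membership
#' across datasets, extracts the consensus set at the minimum count,
#' validates it against the mutual-rank top-K of a held-out (or pooled)
#' dataset, and tests annotation-term overrepresentation of the consensus
#' list with BH-FDR control. All outputs are deterministic functions of the
#' inputs and configuration; a rerun with identical inputs is byte-identical
#' (no timestamps are written).
#'
#' @param config A [run_config()].
#' @param datasets Optional list of [expression_dataset()]; read from
#'   `config$compendium_dir` when `NULL`.
#' @param annotation Optional named list (term -> genes); read from
#'   `config$annotation_path` when `NULL`. `NULL` with no path skips the
#'   enrichment stage.
#' @param validation Optional [expression_dataset()] for mutual-rank
#'   validation; read from the config paths, else the pooled compendium.
#' @return A `coex_run` list: `config`, `filter_report`, `neighbors`
#'   (combined tibble), `consensus` (a `consensus_table`), `consensus_genes`,
#'   `mutual_rank` (a `mutual_rank_table`), `mr_top_set`, `overlap`,
#'   `enrichment`, `enrichment_significant`, `manifest`. Written to
#'   `config$out_dir` when set.
#' @examples
#' cmp <- generate_compendium(compendium_config(n_genes = 150, module_size = 10,
#'                                              n_datasets = 4, seed = 11))
#' ann <- generate_annotation(cmp$truth, n_terms = 10, seed = 11)
#' run <- run_pipeline(run_config("GQRY", k_neighbors = 30, consensus_min_count = 3),
#'                     datasets = cmp$datasets, annotation = ann$annotation)
#' glance(run)
#' @export
run_pipeline <- function(config, datasets = NULL, annotation = NULL,
                         validation = NULL) {
  stopifnot(inherits(config, "run_config"))
  input_files <- character(0)

  if (is.null(datasets)) {
    if (is.null(config$compendium_dir)) {
      abort_config("either `datasets` or `config$compendium_dir` is required")
    }
    input_files <- c(input_files,
                     list.files(config$compendium_dir, full.names = TRUE,
                                pattern = "\\.tsv$"))
    datasets <- read_compendium(config$compendium_dir)$datasets
  }
  if (is.null(annotation) && !is.null(config$annotation_path)) {
    input_files <- c(input_files, config$annotation_path)
    annotation <- read_gmt(config$annotation_path)
  }
  if (is.null(validation)) {
    if (!is.null(config$validation_matrix)) {
      input_files <- c(input_files, config$validation_matrix,
                       config$validation_samples)
      validation <- read_dataset(config$validation_matrix,
                                 config$validation_samples, "validation")
    } else {
      validation <- pool_datasets(datasets, "pooled_validation")
    }
  }

  filter_report <- filter_compendium(datasets, config$query_gene,
                                     config$eta_threshold, config$filter_alpha)
  retained <- filter_report$dataset_id[filter_report$retained]
  if (!length(retained)) {
    abort_compute("no dataset passed the query-consistency filter")
  }
  kept <- datasets[purrr::map_chr(datasets, "dataset_id") %in% retained]

  profiles <- purrr::map(kept, profile_neighbors, query_gene = config$query_gene,
                         k = config$k_neighbors)
  neighbors <- purrr::list_rbind(purrr::map(profiles, tibble::as_tibble))
  consensus <- count_neighbors(profiles)
  min_count <- min(config$consensus_min_count, length(retained))
  consensus_genes <- consensus_set(consensus, min_count)

  mr <- mutual_rank(validation, config$query_gene, k = config$k_neighbors)
  mr_top <- attr(mr, "top_set")
  universe <- setdiff(rownames(validation$values), config$query_gene)
  overlap <- overlap_significance(intersect(consensus_genes, universe),
                                  mr_top, universe)

  enrichment <- NULL
  enrichment_sig <- NULL
  if (!is.null(annotation) && length(consensus_genes)) {
    background <- if (config$background == "annotated") {
      intersect(universe, unique(unlist(annotation)))
    } else {
      universe
    }
    enrichment <- fisher_overrepresentation(
      intersect(consensus_genes, background), annotation, background)
    enrichment_sig <- enrichment_report(enrichment, config$fdr_cutoff)
  }

  manifest <- list(
    tool = "concoex",
    version = as.character(utils::packageVersion("concoex")),
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(input_files)),
    n_datasets = length(datasets),
    retained_datasets = retained,
    consensus_min_count_applied = min_count,
    consensus_size = length(consensus_genes),
    mr_overlap = overlap$overlap_count,
    overlap_significance_note = "hypergeometric p is an extension beyond the raw overlap count"
  )

  run <- structure(list(
    config = config,
    filter_report = filter_report,
    neighbors = neighbors,
    consensus = consensus,
    consensus_genes = consensus_genes,
    mutual_rank = mr,
    mr_top_set = mr_top,
    overlap = overlap,
    enrichment = enrichment,
    enrichment_significant = enrichment_sig,
    manifest = manifest
  ), class = "coex_run")

  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  w(run$filter_report, "filter_report.tsv")
  w(run$neighbors, "neighbors.tsv")
  w(tidy(run$consensus, min_count = run$manifest$consensus_min_count_applied),
    "consensus_counts.tsv")
  writeLines(run$consensus_genes, file.path(dir, "consensus_genes.txt"))
  w(tibble::as_tibble(run$mutual_rank), "mutual_rank.tsv")
  jsonlite::write_json(as.list(run$overlap), file.path(dir, "overlap.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(run$enrichment)) {
    w(run$enrichment, "enrichment.tsv")
    w(run$enrichment_significant, "enrichment_significant.tsv")
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.coex_run <- function(x, ...) {
  cat(sprintf(
    "<coex_run> query '%s': %d/%d datasets retained, consensus %d gene(s), MR overlap %d\n",
    x$config$query_gene, length(x$manifest$retained_datasets),
    x$manifest$n_datasets, x$manifest$consensus_size, x$overlap$overlap_count))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object A `coex_run`.
#' @param ... Unused.
#' @method tidy coex_run
#' @export
tidy.coex_run <- function(x, ...) {
  tidy(x$consensus, min_count = x$manifest$consensus_min_count_applied) |>
    dplyr::left_join(
      tibble::as_tibble(x$mutual_rank)[, c("gene_id", "mutual_rank")],
      by = "gene_id"
    )
}

#' @rdname run_pipeline
#' @method glance coex_run
#' @export
glance.coex_run <- function(x, ...) {
  tibble::tibble(
    query_gene = x$config$query_gene,
    n_datasets = x$manifest$n_datasets,
    n_retained = length(x$manifest$retained_datasets),
    consensus_size = x$manifest$consensus_size,
    mr_overlap = x$overlap$overlap_count,
    mr_overlap_p = x$overlap$hypergeometric_p,
    n_terms_significant = if (!is.null(x$enrichment_significant)) {
      nrow(x$enrichment_significant)
    } else NA_integer_
  )
}

#' Replay externally produced neighbor sheets through the consensus stage
#'
#' Recomputes the consensus count table and the overlap with an external
#' top-K list directly from per-dataset neighbor gene lists, bypassing
#' expression matrices — the path used to re-analyse published
#' supplementary neighbor sheets.
#'
#' @param neighbor_lists Path to a TSV with columns `dataset_id`, `gene_id`
#'   (one row per neighbor per dataset), or a data frame of the same shape.
#' @param external_topk Path to a one-gene-per-line text file (or character
#'   vector): the external top-K coexpression list.
#' @param min_count Consensus threshold, default 4.
#' @param universe Optional character vector for the overlap test; defaults
#'   to the union of all genes seen in either input.
#' @return List with `consensus` (a `consensus_table`), `consensus_genes`,
#'   and `overlap` (tibble from [overlap_significance()]; `NULL` when no
#'   external list is given).
#' @examples
#' sheet <- tibble::tibble(dataset_id = c("d1", "d1", "d2"),
#'                         gene_id = c("a", "b", "a"))
#' replay_sheets(sheet, external_topk = c("a", "z"), min_count = 2)
#' @export
replay_sheets <- function(neighbor_lists, external_topk = NULL,
                          min_count = 4, universe = NULL) {
  sheet <- if (is.character(neighbor_lists)) {
    readr::read_tsv(neighbor_lists, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  } else {
    tibble::as_tibble(neighbor_lists)
  }
  if (!all(c("dataset_id", "gene_id") %in% names(sheet))) {
    abort_parse("neighbor sheet needs columns dataset_id, gene_id (row 1)")
  }
  bad <- which(is.na(sheet$dataset_id) | is.na(sheet$gene_id) |
                 sheet$dataset_id == "" | sheet$gene_id == "")
  if (length(bad)) {
    abort_parse(sprintf("neighbor sheet: empty dataset_id/gene_id (row %d)", bad[1]))
  }
  profiles <- sheet |>
    dplyr::mutate(query_gene = "query") |>
    dplyr::group_split(.data$dataset_id)
  consensus <- count_neighbors(profiles)
  min_count_applied <- min(min_count, length(attr(consensus, "dataset_ids")))
  genes <- consensus_set(consensus, min_count_applied)

  overlap <- NULL
  if (!is.null(external_topk)) {
    ext <- if (length(external_topk) == 1 && file.exists(external_topk)) {
      readLines(external_topk, warn = FALSE)
    } else {
      as.character(external_topk)
    }
    ext <- ext[nzchar(ext)]
    if (is.null(universe)) universe <- union(sheet$gene_id, ext)
    overlap <- overlap_significance(genes, ext, universe)
  }
  list(consensus = consensus, consensus_genes = genes, overlap = overlap)
}
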