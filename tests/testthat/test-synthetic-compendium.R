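small_config <- function(...) {
  compendium_config(n_datasets = 2, n_decoy_datasets = 1, n_genes = 60,
                    module_size = 6, n_conditions = 3,
                    samples_per_condition = 4, seed = 101L, ...)
}

test_that("configuration invariants are enforced with the offending field named", {
  expect_error(compendium_config(module_size = 100, n_genes = 50), "module_size",
               class = "concoex_config_error")
  expect_error(compendium_config(n_conditions = 1), "n_conditions",
               class = "concoex_config_error")
  expect_error(compendium_config(samples_per_condition = 1), "samples_per_condition",
               class = "concoex_config_error")
  expect_error(compendium_config(module_correlation = 0), "module_correlation",
               class = "concoex_config_error")
  expect_error(compendium_config(module_correlation = 1.2), "module_correlation",
               class = "concoex_config_error")
  expect_error(compendium_config(noise_sd = -1), "noise_sd",
               class = "concoex_config_error")
})

test_that("compendium structure matches its configuration and truth", {
  cmp <- generate_compendium(small_config())
  expect_length(cmp$datasets, 3)
  truth <- cmp$truth
  expect_identical(sum(truth$consistent), 2L)
  expect_false(truth$query_gene %in% truth$module_genes)
  for (ds in cmp$datasets) {
    expect_identical(nrow(ds$values), 60L)
    expect_identical(ncol(ds$values), 12L)
    expect_false(anyNA(ds$values))
    expect_true(all(truth$module_genes %in% rownames(ds$values)))
    expect_identical(dplyr::n_distinct(ds$samples$condition), 3L)
  }
})

test_that("identical config and seed give byte-identical serialized compendia", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_compendium(generate_compendium(small_config()), d1)
  write_compendium(generate_compendium(small_config()), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("adding datasets does not perturb earlier datasets", {
  a <- generate_compendium(small_config())
  b <- generate_compendium(compendium_config(
    n_datasets = 2, n_decoy_datasets = 2, n_genes = 60, module_size = 6,
    n_conditions = 3, samples_per_condition = 4, seed = 101L))
  expect_identical(a$datasets[[1]]$values, b$datasets[[1]]$values)
  expect_identical(a$datasets[[3]]$values, b$datasets[[3]]$values)
})

test_that("at module_correlation = 1 every module gene correlates perfectly with the query", {
  cmp <- generate_compendium(small_config(module_correlation = 1))
  for (ds in cmp$datasets) {
    q <- ds$values[cmp$truth$query_gene, ]
    for (g in cmp$truth$module_genes) {
      expect_equal(stats::cor(ds$values[g, ], q), 1, tolerance = 1e-12)
    }
  }
})

test_that("mean module-query correlation matches a Monte-Carlo oracle of the generative model", {
  cfg <- compendium_config(n_datasets = 1, n_decoy_datasets = 0, n_genes = 2000,
                           module_size = 50, module_correlation = 0.8,
                           noise_sd = 1, samples_per_condition = 5,
                           n_conditions = 3, seed = 77L)
  cmp <- generate_compendium(cfg)
  ds <- cmp$datasets[[1]]
  q <- ds$values[cmp$truth$query_gene, ]
  observed <- mean(vapply(cmp$truth$module_genes,
                          function(g) stats::cor(ds$values[g, ], q), 0))

  # Oracle: the same generative equations, written independently - a fresh
  # query draw, standardization, rho-mixing - averaged over 1e4 draws.
  oracle <- withr::with_seed(2024L, {
    n_s <- cfg$n_conditions * cfg$samples_per_condition
    cond <- rep(seq_len(cfg$n_conditions), each = cfg$samples_per_condition)
    mean(replicate(1e4, {
      q_sim <- cfg$effect_size * (cond - 1) + rnorm(n_s, 0, cfg$noise_sd)
      z <- (q_sim - mean(q_sim)) / sd(q_sim)
      x <- cfg$module_correlation * z +
        sqrt(1 - cfg$module_correlation^2) * rnorm(n_s)
      oracle_pearson(x, q_sim)
    }))
  })
  expect_lt(abs(observed - oracle), 0.05)
})

test_that("a zero effect size makes consistent and decoy query rows exchangeable under the filter", {
  # With no condition effect anywhere, "consistent" datasets are retained
  # only at the filter's false-positive rate: over many datasets the
  # retention rate stays near the null level.
  cfg <- compendium_config(n_datasets = 40, n_decoy_datasets = 0, n_genes = 10,
                           module_size = 2, effect_size = 0,
                           samples_per_condition = 4, seed = 33L)
  cmp <- generate_compendium(cfg)
  rep <- filter_compendium(cmp$datasets, "GQRY")
  # null P(retained) = P(eta2 >= 0.5 & p < .05) for F(2, 9) is ~ 2.6%
  expect_lt(mean(rep$retained), 0.25)
})

test_that("datasets round-trip through the TSV dialect", {
  cmp <- generate_compendium(small_config())
  ds <- cmp$datasets[[1]]
  tmp <- withr::local_tempdir()
  write_dataset(ds, file.path(tmp, "m.tsv"), file.path(tmp, "s.tsv"))
  back <- read_dataset(file.path(tmp, "m.tsv"), file.path(tmp, "s.tsv"),
                       ds$dataset_id)
  expect_identical(rownames(back$values), rownames(ds$values))
  expect_identical(back$samples, ds$samples)
  expect_equal(back$values, ds$values, tolerance = 1e-8)
})

test_that("malformed dataset files raise parse errors naming the culprit", {
  tmp <- withr::local_tempdir()
  mp <- file.path(tmp, "m.tsv"); sp <- file.path(tmp, "s.tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), mp)
  writeLines(c("sample_id\tcondition", "s1\tc1", "s2\tc1"), sp)
  expect_error(read_dataset(mp, sp, "x"), "gA", class = "concoex_parse_error")

  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2"), mp)
  writeLines(c("sample_id\tcondition", "s1\tc1", "s9\tc1"), sp)
  expect_error(read_dataset(mp, sp, "x"), "s9", class = "concoex_parse_error")
})

test_that("missing cells read as NA feed pairwise-complete correlation downstream", {
  tmp <- withr::local_tempdir()
  mp <- file.path(tmp, "m.tsv"); sp <- file.path(tmp, "s.tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "q\t1\t2\t3\t4",
               "gA\t2\tNA\t5\t9",
               "gB\t1\t1\t2\t2"), mp)
  writeLines(c("sample_id\tcondition", "s1\tc1", "s2\tc1", "s3\tc2", "s4\tc2"), sp)
  ds <- read_dataset(mp, sp, "x")
  expect_identical(sum(is.na(ds$values)), 1L)
  prof <- profile_neighbors(ds, "q", k = 5)
  # hand-computed r over the complete pairs (s1, s3, s4): q = (1,3,4), gA = (2,5,9)
  r_hand <- oracle_pearson(c(1, 3, 4), c(2, 5, 9))
  expect_equal(prof$r[prof$gene_id == "gA"], r_hand, tolerance = 1e-12)
})

test_that("annotation carries the module as the designated enriched term and round-trips as GMT", {
  cmp <- generate_compendium(small_config())
  ann <- generate_annotation(cmp$truth, n_terms = 8, term_size_range = c(5L, 20L),
                             n_decoy_genes = 5, seed = 9L)
  expect_identical(ann$truth$enriched_term_id, "TERM_MODULE")
  enriched <- ann$annotation$TERM_MODULE
  expect_true(all(cmp$truth$module_genes %in% enriched))
  expect_length(enriched, length(cmp$truth$module_genes) + 5L)
  universe <- c(cmp$truth$query_gene, cmp$truth$module_genes,
                sprintf("BG%05d", 1:53))
  expect_true(all(unlist(ann$annotation) %in% universe))

  tmp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann$annotation, tmp)
  back <- read_gmt(tmp)
  expect_identical(lapply(back, identity)[names(ann$annotation)],
                   ann$annotation)
})

test_that("a single term with zero decoys is exactly the module", {
  cmp <- generate_compendium(small_config())
  ann <- generate_annotation(cmp$truth, n_terms = 1, term_size_range = c(5L, 20L),
                             n_decoy_genes = 0, seed = 4L)
  expect_identical(sort(ann$annotation$TERM_MODULE), sort(cmp$truth$module_genes))
})

test_that("term sizes beyond the genome are rejected", {
  cmp <- generate_compendium(small_config())
  expect_error(generate_annotation(cmp$truth, n_terms = 3,
                                   term_size_range = c(10L, 1000L), seed = 1L),
               "term_size_range", class = "concoex_config_error")
})

test_that("truth JSON round-trips", {
  cmp <- generate_compendium(small_config())
  ann <- generate_annotation(cmp$truth, n_terms = 3, term_size_range = c(5L, 20L),
                             seed = 2L)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_truth(ann$truth, tmp)
  back <- read_truth(tmp)
  expect_identical(back$query_gene, ann$truth$query_gene)
  expect_identical(back$module_genes, ann$truth$module_genes)
  expect_identical(back$enriched_term_id, "TERM_MODULE")
  expect_equal(back$consistent, ann$truth$consistent)
  expect_equal(unclass(back$config), unclass(ann$truth$config))
})
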