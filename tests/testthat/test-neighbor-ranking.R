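test_that("ANOVA filter matches an explicit sums-of-squares oracle on a toy", {
  # conditions {A: 1, 2; B: 5, 6}: SSb = 16, SSw = 1, F = 32
  ds <- toy_dataset(rbind(q = c(1, 2, 5, 6), g2 = c(0, 1, 0, 1)),
                    conditions = c("A", "A", "B", "B"))
  rep <- assess_query_consistency(ds, "q")
  ora <- oracle_anova(c(1, 2, 5, 6), c("A", "A", "B", "B"))
  expect_equal(ora$ss_between, 16)
  expect_equal(ora$ss_within, 1)
  expect_equal(rep$f_statistic, 32)
  expect_equal(rep$f_statistic, ora$f, tolerance = 1e-12)
  expect_equal(rep$p_value, ora$p, tolerance = 1e-12)
  expect_equal(rep$eta_squared, ora$eta_squared, tolerance = 1e-12)
  expect_true(rep$retained)
})

test_that("degenerate query rows are handled: constant row gives eta 0, perfect separation gives eta 1", {
  const <- toy_dataset(rbind(q = rep(3, 6), g2 = rnorm(6)),
                       conditions = rep(c("A", "B", "C"), each = 2))
  rep <- assess_query_consistency(const, "q")
  expect_equal(rep$eta_squared, 0)
  expect_false(rep$retained)

  sep <- toy_dataset(rbind(q = rep(c(1, 2, 3), each = 2), g2 = rnorm(6)),
                     conditions = rep(c("A", "B", "C"), each = 2))
  # a perfect fit trips R's "unreliable F-test" warning; the report is exact
  rep <- suppressWarnings(assess_query_consistency(sep, "q"))
  expect_equal(rep$eta_squared, 1)
  expect_lt(rep$p_value, 1e-10)
  expect_true(rep$retained)
})

test_that("filter errors: absent query gene, too few usable conditions", {
  ds <- toy_dataset(rbind(q = 1:4, g2 = 4:1), conditions = c("A", "A", "B", "B"))
  expect_error(assess_query_consistency(ds, "nope"), "nope",
               class = "concoex_lookup_error")
  one_cond <- toy_dataset(rbind(q = 1:4, g2 = 4:1),
                          conditions = rep("A", 4))
  expect_error(assess_query_consistency(one_cond, "q"),
               class = "concoex_structural_error")
})

test_that("profile neighbors match a direct-formula Pearson oracle and its ranking", {
  m <- rbind(
    q  = c(2, 4, 4, 6),
    gA = c(1, 2, 3, 4),
    gB = c(6, 4, 4, 2),
    gC = c(1, 9, 2, 8),
    gD = c(5, 5, 6, 5)
  )
  ds <- toy_dataset(m)
  prof <- profile_neighbors(ds, "q", k = 4)
  for (g in c("gA", "gB", "gC", "gD")) {
    expect_equal(prof$r[prof$gene_id == g], oracle_pearson(m["q", ], m[g, ]),
                 tolerance = 1e-12, label = g)
  }
  ora_r <- vapply(c("gA", "gB", "gC", "gD"),
                  function(g) oracle_pearson(m["q", ], m[g, ]), 0)
  expect_identical(prof$gene_id, names(sort(-ora_r)))
  expect_identical(prof$rank, 1:4)
  expect_true(all(diff(prof$r) <= 0))
})

test_that("a gene duplicating the query row gets r = 1 and rank 1", {
  ds <- toy_dataset(rbind(q = c(1, 3, 2, 5), copy = c(1, 3, 2, 5),
                          other = c(4, 1, 1, 2)))
  prof <- profile_neighbors(ds, "q", k = 2)
  expect_identical(prof$gene_id[1], "copy")
  expect_equal(prof$r[1], 1, tolerance = 1e-12)
})

test_that("exact correlation ties are broken by gene id ascending", {
  base <- c(1, 2, 3, 4)
  ds <- toy_dataset(rbind(q = base, zz = 2 * base + 1, aa = 3 * base - 2))
  prof <- profile_neighbors(ds, "q", k = 2)
  expect_identical(prof$gene_id, c("aa", "zz"))
  expect_identical(prof$rank, 1:2)
})

test_that("zero-variance and short genes are skipped and logged, not ranked", {
  m <- rbind(q = c(1, 2, 3, 4), flat = c(7, 7, 7, 7),
             holey = c(1, NA, NA, NA), ok = c(2, 2, 5, 7))
  ds <- toy_dataset(m)
  prof <- profile_neighbors(ds, "q", k = 10)
  expect_identical(prof$gene_id, "ok")
  skipped <- attr(prof, "skipped")
  expect_setequal(skipped$gene_id, c("flat", "holey"))
  expect_identical(skipped$reason[skipped$gene_id == "flat"], "zero_variance")
  expect_identical(skipped$reason[skipped$gene_id == "holey"], "lt3_complete_pairs")
  expect_identical(attr(prof, "genes_evaluated"), 1L)

  all_bad <- toy_dataset(rbind(q = c(1, 2, 3), flat = c(1, 1, 1)))
  expect_error(profile_neighbors(all_bad, "q", k = 5),
               class = "concoex_compute_error")
})

test_that("sample permutation leaves filter report and neighbor profile unchanged", {
  cmp <- generate_compendium(compendium_config(
    n_datasets = 1, n_decoy_datasets = 0, n_genes = 40, module_size = 5,
    samples_per_condition = 4, seed = 55L))
  ds <- cmp$datasets[[1]]
  perm <- withr::with_seed(1, sample(ncol(ds$values)))
  ds_perm <- expression_dataset(ds$values[, perm], ds$samples[perm, ],
                                ds$dataset_id)
  rep_a <- assess_query_consistency(ds, "GQRY")
  rep_b <- assess_query_consistency(ds_perm, "GQRY")
  expect_equal(rep_a, rep_b, tolerance = 1e-12)
  prof_a <- profile_neighbors(ds, "GQRY", k = 10)
  prof_b <- profile_neighbors(ds_perm, "GQRY", k = 10)
  expect_identical(prof_a$gene_id, prof_b$gene_id)
  expect_equal(prof_a$r, prof_b$r, tolerance = 1e-12)
})

test_that("gene row permutation only reorders ties per the stated tie-break", {
  cmp <- generate_compendium(compendium_config(
    n_datasets = 1, n_decoy_datasets = 0, n_genes = 30, module_size = 4,
    samples_per_condition = 3, seed = 66L))
  ds <- cmp$datasets[[1]]
  perm <- withr::with_seed(2, sample(nrow(ds$values)))
  ds_perm <- expression_dataset(ds$values[perm, ], ds$samples, ds$dataset_id)
  prof_a <- profile_neighbors(ds, "GQRY", k = 29)
  prof_b <- profile_neighbors(ds_perm, "GQRY", k = 29)
  expect_identical(prof_a$gene_id, prof_b$gene_id)
})

test_that("positive affine transforms of the query preserve the ranking; negative ones flip r", {
  cmp <- generate_compendium(compendium_config(
    n_datasets = 1, n_decoy_datasets = 0, n_genes = 30, module_size = 4,
    samples_per_condition = 3, seed = 77L))
  ds <- cmp$datasets[[1]]
  prof0 <- profile_neighbors(ds, "GQRY", k = 29)

  scaled <- ds$values
  scaled["GQRY", ] <- 2.5 * scaled["GQRY", ] + 7
  prof_pos <- profile_neighbors(
    expression_dataset(scaled, ds$samples, ds$dataset_id), "GQRY", k = 29)
  expect_identical(prof_pos$gene_id, prof0$gene_id)
  expect_equal(prof_pos$r, prof0$r, tolerance = 1e-12)

  flipped <- ds$values
  flipped["GQRY", ] <- -1.5 * flipped["GQRY", ] + 3
  prof_neg <- profile_neighbors(
    expression_dataset(flipped, ds$samples, ds$dataset_id), "GQRY", k = 29)
  by_gene <- stats::setNames(prof_neg$r, prof_neg$gene_id)
  expect_equal(unname(by_gene[prof0$gene_id]), -prof0$r, tolerance = 1e-12)
})

test_that("spearman is available as the alternative neighbor metric", {
  m <- rbind(q = c(1, 2, 3, 10), mono = c(1, 4, 9, 11), anti = c(4, 3, 2, 1))
  prof <- profile_neighbors(toy_dataset(m), "q", k = 2, method = "spearman")
  expect_equal(prof$r[prof$gene_id == "mono"], 1, tolerance = 1e-12)
  expect_equal(prof$r[prof$gene_id == "anti"], -1, tolerance = 1e-12)
})
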