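#' Specific lysis from europium-release fluorescence
#'
#' Percent specific lysis of labeled target cells:
#' `100 * (experimental - spontaneous) / (total - spontaneous)`, where the
#' three values are fluorescence readings of released label for the
#' experimental well, the spontaneous-release control and the full-lysis
#' (detergent) control. Values outside \[0, 100\] are reported as-is with a
#' QC flag, never clipped. The ratio is invariant to rescaling all three
#' readings by a common positive factor.
#'
#' @param wells Data frame with numeric columns `experimental`,
#'   `spontaneous`, `total` (one row per well); any further columns (e.g. a
#'   `label` for the effector:target ratio or antibody condition) are carried
#'   through.
#' @return Tibble: the input columns plus `lysis_pct` and `qc_flag`
#'   (`"ok"` or `"out_of_range"`).
#' @examples
#' specific_lysis(data.frame(label = "E:T 5", experimental = 600,
#'                           spontaneous = 200, total = 1000))
#' @export
specific_lysis <- function(wells) {
  wells <- tibble::as_tibble(wells)
  need <- c("experimental", "spontaneous", "total")
  if (!all(need %in% names(wells))) {
    abort_input("`wells` needs columns experimental, spontaneous, total")
  }
  vals <- wells[need]
  if (any(is.na(unlist(vals))) || any(unlist(vals) < 0)) {
    abort_input("release values must be non-negative and non-missing")
  }
  if (any(wells$total <= wells$spontaneous)) {
    bad <- which(wells$total <= wells$spontaneous)[1]
    abort_input(sprintf(
      "degenerate controls in row %d: total release must exceed spontaneous release",
      bad))
  }
  wells |>
    dplyr::mutate(
      lysis_pct = 100 * (.data$experimental - .data$spontaneous) /
        (.data$total - .data$spontaneous),
      qc_flag = ifelse(.data$lysis_pct < 0 | .data$lysis_pct > 100,
                       "out_of_range", "ok")
    )
}

#' Comparative delta-delta-Ct relative quantification
#'
#' Fold change of a target transcript in a case group relative to a
#' reference group, normalized to a housekeeping gene set:
#' `dCt(group) = mean Ct(target) - mean over housekeeping genes of mean
#' Ct(hk)`; `ddCt = dCt(case) - dCt(reference)`; `fold = 2^-ddCt`. Averaging
#' housekeeping Ct arithmetically equals geometric-mean normalization in
#' expression space.
#'
#' @param case,reference Data frames with columns `gene` and `ct` (one row
#'   per replicate; Ct in cycles, > 0).
#' @param target_gene Target transcript gene id.
#' @param housekeeping Character vector of housekeeping gene ids, e.g.
#'   `c("ACTB", "GAPDH", "RNA18S", "RNA28S")`; every one must appear in both
#'   tables.
#' @return One-row tibble: `target_gene`, `dct_case`, `dct_reference`,
#'   `ddct`, `fold_change`.
#' @examples
#' ct <- data.frame(gene = c("T", "HK1", "HK2"), ct = c(24, 20, 22))
#' ref <- data.frame(gene = c("T", "HK1", "HK2"), ct = c(26, 20, 22))
#' ddct_relative(ct, ref, "T", c("HK1", "HK2"))
#' @export
ddct_relative <- function(case, reference, target_gene, housekeeping) {
  dct <- function(tbl, who) {
    tbl <- tibble::as_tibble(tbl)
    if (!all(c("gene", "ct") %in% names(tbl))) {
      abort_input(sprintf("%s table needs columns gene, ct", who))
    }
    if (any(is.na(tbl$ct)) || any(tbl$ct <= 0)) {
      abort_input(sprintf("%s table: Ct values must be positive", who))
    }
    for (g in c(target_gene, housekeeping)) {
      if (!g %in% tbl$gene) {
        abort_lookup(sprintf("gene '%s' missing from %s table", g, who))
      }
    }
    gene_means <- tbl |>
      dplyr::filter(.data$gene %in% c(target_gene, housekeeping)) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(mean_ct = mean(.data$ct), .groups = "drop")
    target_ct <- gene_means$mean_ct[gene_means$gene == target_gene]
    hk_ct <- mean(gene_means$mean_ct[gene_means$gene %in% housekeeping])
    target_ct - hk_ct
  }
  dct_case <- dct(case, "case")
  dct_ref <- dct(reference, "reference")
  ddct <- dct_case - dct_ref
  tibble::tibble(
    target_gene = target_gene,
    dct_case = dct_case,
    dct_reference = dct_ref,
    ddct = ddct,
    fold_change = 2^(-ddct)
  )
}

#' Summarise repeated NK cell counts per group
#'
#' Per-group summary of repeated absolute NK cell counts (cells/mL):
#' mean and SD over all visit-level measurements, the fraction of
#' measurements strictly below a severe-lymphopenia cutoff, and — where
#' per-visit CD56-dim and CD56-bright counts are present — the per-visit
#' dim/bright ratio summarised by its mean. The lymphopenia fraction is
#' computed over visit-level measurements, not per subject. A visit with
#' `bright_count = 0` has an undefined ratio; it is excluded and counted in
#' `n_ratio_undefined`.
#'
#' @param counts Data frame with columns `subject`, `group`, `nk_count`
#'   and optionally `dim_count`, `bright_count` (one row per visit).
#' @param lymphopenia_cutoff Severe-lymphopenia threshold in cells/mL,
#'   default `50e3`.
#' @return Tibble, one row per group: `group`, `n_subjects`, `n_visits`,
#'   `mean_count`, `sd_count`, `frac_below_cutoff`, `mean_dim_bright_ratio`,
#'   `n_ratio_defined`, `n_ratio_undefined`.
#' @examples
#' nk_summary(data.frame(subject = c("p1", "p1", "u1"),
#'                       group = c("affected", "affected", "unaffected"),
#'                       nk_count = c(40e3, 60e3, 300e3)))
#' @export
nk_summary <- function(counts, lymphopenia_cutoff = 50e3) {
  counts <- tibble::as_tibble(counts)
  if (!all(c("subject", "group", "nk_count") %in% names(counts))) {
    abort_input("`counts` needs columns subject, group, nk_count")
  }
  if (!nrow(counts)) abort_input("`counts` is empty")
  if (any(is.na(counts$nk_count)) || any(counts$nk_count < 0)) {
    abort_input("nk_count must be non-negative and non-missing")
  }
  if (!"dim_count" %in% names(counts)) counts$dim_count <- NA_real_
  if (!"bright_count" %in% names(counts)) counts$bright_count <- NA_real_
  counts |>
    dplyr::mutate(
      ratio_defined = !is.na(.data$dim_count) & !is.na(.data$bright_count) &
        .data$bright_count > 0,
      ratio_undefined = !is.na(.data$dim_count) & !is.na(.data$bright_count) &
        .data$bright_count == 0,
      ratio = ifelse(.data$ratio_defined,
                     .data$dim_count / .data$bright_count, NA_real_)
    ) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_subjects = dplyr::n_distinct(.data$subject),
      n_visits = dplyr::n(),
      mean_count = mean(.data$nk_count),
      sd_count = stats::sd(.data$nk_count),
      frac_below_cutoff = mean(.data$nk_count < lymphopenia_cutoff),
      mean_dim_bright_ratio = if (any(.data$ratio_defined)) {
        mean(.data$ratio[.data$ratio_defined])
      } else NA_real_,
      n_ratio_defined = sum(.data$ratio_defined),
      n_ratio_undefined = sum(.data$ratio_undefined),
      .groups = "drop"
    )
}

#' Welch two-group comparison
#'
#' Heteroscedastic (Welch) t test between two groups with
#' Welch-Satterthwaite degrees of freedom. The tail choice is explicit and
#' has no default: analyses vary per comparison, so a silent default would
#' be a trap.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param alternative `"two.sided"`, `"greater"` (mean of A greater) or
#'   `"less"`; required.
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `alternative`.
#' @examples
#' two_group_tests(c(1, 2, 3, 4), c(2, 4, 6, 8), alternative = "two.sided")
#' @export
two_group_tests <- function(values_a, values_b,
                            alternative = c("two.sided", "greater", "less")) {
  if (missing(alternative)) {
    abort_config("`alternative` must be given explicitly ('two.sided', 'greater' or 'less')")
  }
  alternative <- match.arg(alternative)
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort_input("each group needs at least 2 values")
  }
  fit <- stats::t.test(values_a, values_b, alternative = alternative,
                       var.equal = FALSE)
  tibble::tibble(
    t_statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    mean_a = mean(values_a),
    mean_b = mean(values_b),
    alternative = alternative
  )
}
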