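---
title: "Methods: consensus coexpression with mutual-rank validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus coexpression with mutual-rank validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concoex)
```

## The model and its assumptions

`concoex` operationalizes a consensus coexpression screen: a gene is called
a partner of the query not because it correlates strongly in one dataset,
but because it keeps re-appearing among the query's top-K correlation
neighbors across independent datasets. The underlying assumptions are
modest: (i) expression values within one dataset are on a common,
monotone-in-abundance scale (we declare log2 throughout; Pearson
correlation is not invariant to log transforms, so one convention has to be
fixed); (ii) datasets are independent enough that repeated top-K membership
is unlikely under the null — for D retained datasets and a genome of G
genes, a background gene's expected count is roughly D·K/(G−1), so with
D = 6, K = 200, G = 2000 a count ≥ 4 is far out in the binomial tail;
(iii) condition structure, not within-condition noise, carries the query's
signal — which is what the consistency filter screens for.

### Stage by stage

**Consistency filter.** Public repository profile queries are typically
curated by eye: keep datasets where the query is stable within conditions
and clearly different between them. We replace that judgement with a
one-way ANOVA of the query row on the condition factor, summarised by
η² = SS_between/SS_total and the F-test p-value, retaining a dataset when
η² ≥ 0.5 **and** p < 0.05. η² captures "most of the query's variance is
between conditions" (the visual impression of consistent levels); the
p-value guards against small-sample flukes. Both thresholds are exposed.
A query row with SS_total = 0 is defined to have η² = 0 and is never
retained. Filtering happens **before** neighbor collection; only retained
datasets contribute profiles and the denominator of the consensus count is
the retained set. Both choices are recorded in the run manifest.

**Profile neighbors.** Pearson correlation of the query row against every
other gene over pairwise-complete samples, ranked by *signed* r descending:
the analysis targets coexpression, so a strong negative correlate is not a
neighbor. Spearman is available as an alternative metric for heavy-tailed
data. Genes with fewer than 3 complete pairs (the smallest n for which r
has a degree of freedom) or zero variance on those pairs are excluded and
reported in a skip log rather than silently dropped. Ties in r are broken
by gene id ascending — an arbitrary but deterministic rule, without which
the downstream consensus count would not be reproducible across platforms.

**Consensus.** The score is the simple count of datasets, not a weighted
sum of ranks or correlations: weights would re-introduce exactly the
cross-platform comparability problems the count avoids. "In more than 3
datasets" is implemented literally as count ≥ 4 and exposed as
`consensus_min_count`. Output ordering (count descending, then gene id) is
our choice, made for stable diffs.

**Mutual-rank validation.** An independent axis of evidence:
MR(A,B) = √(rank_A(B)·rank_B(A)) with both rank lists by signed Pearson
descending, the convention of precomputed coexpression databases. MR is
symmetric in the pair and punishes one-sided attraction (a gene that ranks
the query highly but is itself buried in the query's list). The validation
compendium here is a single pooled dataset — all input datasets' samples
concatenated, with per-dataset baselines retained. That makes the check
conservative: between-dataset baseline shifts dilute pooled correlations,
so even true module genes achieve only partial MR top-K overlap (the
worked example in the README shows 17/50). The hypergeometric p attached
to the overlap is flagged in the manifest as an extension: the raw overlap
count is the primary statistic.

**Overrepresentation.** One-sided Fisher's exact test per term (the upper
hypergeometric tail — enrichment, never depletion), BH-FDR across the
tested terms, report cutoff q < 0.05. The background universe defaults to
*all* genes of the compendium; because annotation pipelines differ on
whether the universe is all genes or annotated genes, a flag covers both.
Terms are intersected with the background before testing, but a *list* gene
absent from the background is a hard error — a silently shrunken list is
the classic way enrichment analyses go wrong.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `k_neighbors` | 200 | genes | standard top-K size for profile-neighbor queries |
| `consensus_min_count` | 4 | datasets | "more than 3 datasets", read strictly |
| `eta_threshold` | 0.5 | fraction of variance | "most variance between conditions" |
| `filter_alpha` | 0.05 | significance | conventional |
| `fdr_cutoff` | 0.05 | FDR | conventional report threshold |
| `effect_size` | 2 | log2 units / condition step | a 4-fold shift, typical of a clear subgroup effect |
| `module_correlation` | 0.9 | Pearson ρ | strong co-regulation target |
| `noise_sd` | 1 | log2 units | typical residual spread of log-scale expression |
| `n_conditions` × `samples_per_condition` | 3 × 8 | — | typical repository series subgroup sizes |

## What the generator emulates — and what it does not

`generate_compendium()` draws, per dataset: a per-gene baseline
N(8, 2) (log2 scale); a query row `baseline + effect_size·(condition−1) +
N(0, noise_sd)` (effect zero in decoy datasets); module genes
`ρ·z + √(1−ρ²)·ε` on the standardized realized query profile z, rescaled
by `noise_sd` — so at ρ = 1 a module gene is an affine image of the query
and correlates exactly 1; independent background genes. Each dataset draws
from its own substream of the seed, so enlarging a compendium never
perturbs existing datasets.

This is a deliberately minimal Gaussian latent-factor model. It emulates:
multiple datasets with condition structure, a query whose consistency
varies by dataset, a co-regulated module of tunable strength, and an
annotation with one known enriched term. It does **not** emulate: platform
and probe effects, mean–variance coupling of counts, correlated background
modules, missing values (permitted on read, never generated), batch
structure within a dataset, or outlier samples. Passing tests therefore
demonstrate that the pipeline's logic is correct and well-calibrated under
clean conditions — not that the default thresholds are optimal for any
particular real compendium.

## Numerical and degenerate-input choices

- Correlations use `stats::cor` with pairwise-complete observations;
  eligibility (≥ 3 complete pairs, nonzero variance) is established before
  ranking so that skipped genes can never occupy a rank.
- All ranking tie-breaks are lexicographic on gene id; mutual-rank sorting
  breaks MR ties the same way.
- Fisher/overlap p-values use the closed-form hypergeometric tail
  (`phyper`); the test suite checks them against exhaustive
  binomial-coefficient tail summation to 12 significant digits for
  universes ≤ 60, and against `fisher.test` as an independent library
  cross-check.
- BH adjustment delegates to `p.adjust(method = "BH")` behind an input
  guard (p ∈ (0,1]); the suite verifies the hand-applied step-up rule and
  permutation invariance.
- Specific lysis outside [0, 100]% is reported as-is with a QC flag —
  clipping would hide pipetting or labeling problems. Controls with
  total ≤ spontaneous release are an error, not a NaN.
- ΔΔCt aggregates multiple housekeeping genes by the arithmetic mean of
  their mean Ct, equivalent to geometric-mean normalization in expression
  space — the standard multi-reference-gene convention.
- The severe-lymphopenia fraction is computed over visit-level
  measurements, not per subject, matching how repeated clinical counts are
  summarised against a threshold.
- Welch two-group tests require the tail choice explicitly; analyses that
  mix one- and two-tailed comparisons per figure are too easy to get wrong
  with a silent default.
- Matrix TSVs serialize values at 9 significant digits; write∘read is the
  identity at that precision, and the determinism tests hash stage outputs
  byte-for-byte (manifests exclude timestamps — none are written).

## Problem sizes used by the test and acceptance suites

Module tests run on toys of ≤ 6 genes (where exact oracles are feasible)
and compendia of 30–300 genes. The recovery experiment uses the default
study conditions — 6 consistent + 3 decoy datasets, 2000 genes, a 50-gene
module at ρ = 0.9, K = 200, count ≥ 4 — averaged over 20 replicate
compendia; these sizes were chosen as the smallest at which top-K overlap
statistics behave like a realistically sized genome. An a-priori power
check guided the 3 × 8 design: under the null, P(η² ≥ 0.5 and p < 0.05)
for F(2, 21) is ≈ 7×10⁻⁴, so three decoys across 20 replicates are
expected to produce no false retentions, while the ρ = 0.9 module at n=24
samples is recovered with near-certainty.

## Known limitations

- The consistency filter assumes a usable condition factor; datasets with
  continuous covariates need pre-binning.
- Mutual-rank validation materialises the full gene × gene correlation
  matrix (guarded by `max_genes`, default 6000); genome-scale MR needs a
  blocked implementation.
- Replaying published neighbor sheets reproduces counting and overlap
  exactly, but recomputing the sheets themselves requires the original
  repository data and is out of scope.
- One query gene per run; no partial correlations or network inference —
  the consensus count is intentionally simple.
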