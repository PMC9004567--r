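---
title: "Dual-purpose aging/disease target discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-purpose aging/disease target discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gerotarget)
```

## The problem

Many chronic diseases — neurodegeneration, fibrosis, metabolic and chronic
inflammatory disease — share age as their dominant risk factor. A gene that
is highly prioritized as a drug target across several such age-associated
diseases (AADs), but not across diseases whose onset is largely independent
of age (NAADs), and that is dysregulated in a consistent direction across
AAD classes, is a plausible *dual-purpose* target: modulating it may treat
the disease and engage an aging mechanism at the same time.

`gerotarget` implements this reasoning as a reusable pipeline over two
inputs that upstream prioritization engines or differential-expression
workflows produce anyway:

1. **Ranked target lists** — per disease, the top-ranked genes under a
   novelty setting (ranks 1..100 by default);
2. **Comparison records** — one log fold change (logFC) per gene per
   case-control comparison, with each comparison tagged by disease,
   disease class and AAD/NAAD category.

The default disease layout (`disease_registry()`) comprises 14 AADs with 87
case-control comparisons and 19 NAADs with 126 comparisons, spread over
five disease classes; the infectious class occurs only among NAADs, so the
AAD-side consistency analysis never encounters it.

## Cross-disease aggregation

`combine_lists()` scores every gene that appears in at least one disease's
top-`rank_cap` list by two keys:

* **occurrence** — the number of diseases whose capped list contains the
  gene (descending), then
* **mean rank** — the average of the gene's ranks over exactly those
  diseases (ascending), then
* the gene symbol (ascending) as a deterministic final tie-break.

Two choices deserve emphasis because they are easy to get silently wrong.
First, the mean rank averages only over diseases where the gene occurs;
absence affects occurrence, not the mean, so occurrence strictly dominates
the ordering. Second, entries beyond `rank_cap` are *excluded*, not clamped
to the cap: a gene ranked 150th in some disease contributes nothing there.

`select_top()` cuts the ordered table (top 100 by default), and
`classify_targets()` splits the AAD and NAAD top lists by set algebra into
AAD-specific, common, and NAAD-specific targets. AAD-specific genes are the
age-associated candidates; common genes are interpreted as broadly
disease-relevant.

## Expression consistency and the dual-purpose filter

For each gene and AAD disease class, `consistency_profiles()` computes the
fraction of that class's comparisons with logFC above zero and below zero.
A class is called `up` (or `down`) when the corresponding fraction reaches
the threshold, 0.60 by default and **inclusive**: 3 of 5 comparisons is a
call. A logFC of exactly zero counts toward neither direction — a sign
statistic should not credit absent change. Because only the sign enters,
the statistic is invariant to positive rescaling of logFC, and the package
is deliberately agnostic about the logarithm base of the input logFC.

`dual_purpose_filter()` retains genes called in the same direction in at
least `min_classes` (default 2) disease classes. A gene that reaches the
class minimum in *both* directions is emitted once per direction with an
`ambiguous` flag rather than silently dropped.

Missing (gene, comparison) records are simply absent from the denominators;
the profile reports `n_comparisons` per class so downstream users can judge
the support of each call.

`compare_logfc_groups()` complements the sign statistic with a two-tailed
two-sample t-test of a gene's logFC between AAD and NAAD comparisons. The
Welch (unequal-variance) variant is the default because the two category
pools differ in size and in disease composition, so equal variances should
not be assumed; `var.equal = TRUE` restores the classical Student test.
`compare_logfc_table()` appends Benjamini–Hochberg adjusted values for
reference, but no filter in the pipeline consumes them.

## Hypergeometric enrichment

Overlap between a target list and a curated aging-gene pool is judged
against the druggable background. With `N` background genes, `K` pool
genes, `n` targets and observed overlap `r`,

$$p = 1 - \sum_{i=0}^{r-1} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}
    = P(X \ge r),$$

together with the expected overlap $nK/N$ and fold enrichment $r/(nK/N)$.
The tail **includes** $r$ itself (the sum stops at $r-1$); the off-by-one
alternative convention is the classic enrichment bug. Numerical notes:

* Binomial coefficients are evaluated through `lchoose` (log-gamma); the
  default background of 5,626 genes overflows naive factorials.
* The upper tail is summed directly in log space with a log-sum-exp.
  Complementing the lower sum ($1-\sum_{i<r}$) would cancel
  catastrophically exactly when $p$ is small — the regime enrichment cares
  about.
* The result is clamped to $[0,1]$ against round-off; `r = 0` returns
  exactly 1 (empty sum).

The background size is a property of the pool (`gene_pool()`), not a
constant: 5,626 is only the default, mirroring the druggable universe of
the study design the package emulates.

```{r}
hypergeom_enrichment(N = 5626, K = 62, n = 100, r = 14)
```

## Hallmarks and candidate selection

Hallmark-of-aging assignments are literature-derived and therefore enter
the pipeline as an *input* table (12-term closed vocabulary: the nine
classic hallmarks plus extracellular matrix stiffness, inflammation and
retrotranspositions). `summarize_hallmarks()` produces per-hallmark counts
and the multi-hallmark and all-hallmark gene sets over a target list.

`select_candidates()` is a deterministic conjunctive rule engine: keep a
gene iff it has at least one hallmark, a dual-purpose call, no safety flag,
and is not a cancer driver slated for antagonism (a pro-aging role implies
an antagonist therapy; antagonizing a flagged driver — e.g. a tumor
suppressor — is excluded). Each criterion is an independent toggle, and
disabling any single one can only enlarge the output (a property the tests
assert). The pro/anti-aging role, driver status and safety evidence are
manual-curation columns, not computed quantities; the package draws the
consequences of the annotations, it does not create them.

## The synthetic-data generator

Real inputs of this kind come from proprietary prioritization engines and
curated annotation work, so the package ships a seeded generator
(`sim_config()`, `gen_ranked_lists()`, `gen_comparisons()`) that emulates
the *statistical structure* the pipeline assumes, with planted ground truth
so every stage is verifiable end to end.

* **Ranked lists.** Null genes are ordered uniformly at random per disease.
  Each planted gene relevant to the disease (AAD-planted genes in AAD
  diseases; common-planted genes everywhere) is inserted into that ordering
  after $G \sim \mathrm{Geometric}(p)$ null genes, so its within-disease
  rank is geometrically concentrated near the top. We chose this insertion
  construction over overlaying continuous scores because it makes the
  degenerate limits exact — at $p = 1$ planted genes occupy the first ranks
  with certainty — while keeping the same latent-ordering semantics.
* **logFC.** Null logFC is centred Gaussian noise with sd
  `noise_logfc_sd`. A planted, category-relevant gene draws
  $s\,\lvert\mathcal N(\mu, \sigma)\rvert$ where the sign $s$ equals the
  planted direction with probability `planted_sign_prob` exactly; the
  magnitude and the sign are decoupled so the per-comparison sign-agreement
  probability is exact by construction, not approximately induced by a mean
  shift.
* **Determinism.** All randomness flows through named substreams derived
  from the single config seed (one per disease and purpose), so a fixed
  seed reproduces every file byte for byte and individual diseases can be
  regenerated without replaying the whole stream.

Default parameters, chosen once as a realistic regime for this kind of
data: a 5,626-gene universe matching the default enrichment background;
the 14 + 19 disease layout with its per-disease comparison counts; 30
AAD-planted plus 30 common-planted genes (enough to populate a top-100
list without saturating it); `planted_sign_prob = 0.9` (strong but
imperfect cross-cohort agreement); `planted_rank_geometric_p = 0.05`,
i.e. a mean within-disease rank of about 20 and ≈ 0.994 probability of
entering a relevant top-100 list — a strongly but not perfectly
prioritized target; logFC noise sd 1.0 and planted magnitude 1.5, a
moderate effect on the log scale.

What the generator does **not** emulate: correlation between comparisons of
the same dataset or tissue, platform-dependent gene missingness, batch
effects, age covariates, or any realistic structure in *which* genes are
prioritized (gene identities are exchangeable labels). Passing recovery
tests therefore demonstrate that the pipeline's logic is correct and well
calibrated under its own model assumptions — not that those assumptions
hold for any particular real dataset.

## Verification strategy and problem sizes

The test suite checks each stage against an independent oracle: a pairwise
comparison sort for aggregation order, exhaustive draw enumeration and
exact integer arithmetic for the hypergeometric tail (plus `phyper` as an
independent cross-check), brute-force sign counting and exhaustive
class-subset search for the consistency filter, and a literal restatement
of the conjunctive rule for candidate selection. End-to-end, the default
simulation is run over 20 seeds and planted AAD genes must be recovered in
the AAD-specific dual-purpose set with mean sensitivity at least 0.8 at a
null false-positive rate at most 0.05, with a planted-gene pool enriched
(fold > 1, p < 0.01) in at least 95% of seeds; these figures are
generator-design targets for the package's own calibration, not empirical
claims about external data. Unit tests run on reduced layouts (a 4-disease
registry, universes of a few hundred genes) so the whole suite completes
in minutes on one CPU.

## Known limitations

* Occurrence is computed over the top-`rank_cap` slice of each disease
  list; if upstream tools export deeper lists, the cap is the user's
  statement of what "prioritized" means.
* The consistency statistic ignores effect magnitude entirely; a gene with
  many tiny same-sign logFC values passes as readily as one with large
  shifts. The t-test output is the magnitude-aware complement.
* Per-gene t-tests are reported without multiplicity-based filtering by
  design; the BH column is informational.
* The rule engine reproduces a *reasoning scheme* over curated inputs; it
  cannot reproduce judgment calls that were never encoded in those inputs.
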