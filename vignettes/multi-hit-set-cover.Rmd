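---
title: "Finding multi-hit gene combinations by weighted set cover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding multi-hit gene combinations by weighted set cover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitcover)
```

## The model

Carcinogenesis is widely understood to require a small number of
cooperating mutations — "hits" — rather than a single driver event;
mathematical models of cancer incidence place the required number
somewhere between two and eight depending on the cancer type. `hitcover`
searches for *multi-hit combinations*: sets of `h` genes such that a
sample carrying a protein-altering somatic mutation in **every** gene of
the set is classified as tumor. A sample carrying mutations in all genes
of a combination is said to be *covered* by it.

Given a cohort of `N_t` tumor and `N_n` normal samples with binary
gene-mutation profiles, the discovery problem is cast as weighted set
cover (WSC): the universe is the set of tumor samples, each candidate
h-gene combination covers the tumors mutated in all of its genes, and the
goal is a minimum-total-weight family of combinations covering every
tumor. Each candidate's weight is the inverse of a scaled accuracy,

$$w_i \;=\; \left(\frac{\alpha\,TP_i + TN_i}{N_t + N_n}\right)^{-1},
\qquad 0 \le \alpha \le 1,$$

where `TP` counts tumors covered by the combination and `TN` normals
*not* covered. Low weight means the combination covers many tumors while
sparing normals — high likelihood of being carcinogenic. The scaling
factor `alpha` balances sensitivity against specificity: because a full
cover always attains sensitivity 1.0 on the cohort it was fitted to,
`alpha` is kept small (default 0.1) so that candidate selection is driven
mostly by specificity.

Exact WSC is intractable here: with `G = 20000` genes and up to `h = 8`
hits there are `search_space_size(20000, 8)` ≈ 6×10²⁹ candidate
combinations, and the optimum ranges over all subsets of them. `hit_cover()`
therefore uses the standard greedy approximation, iterating until every
tumor is covered:

1. recompute every candidate's confusion counts and weight **over the
   still-active (unselected) samples only**;
2. select the candidate with minimum weight;
3. deactivate the samples it covers.

Its cost is O(N·M) — `greedy_complexity(20000, N = 200, h_max = 2)`
≈ 4×10¹⁰ for pairs, which is why the practical default is `h = 2`;
genome-scale `h ≥ 3` is outside what this exhaustive-enumeration fitter
is meant for.

## Interpretation choices in the greedy step

The algorithm statement leaves several details open; the package fixes
them as follows.

* **Iteration-local totals.** `N_t` and `N_n` in the weight are the
  *active* totals at the current iteration, consistent with computing
  `TP`/`TN` over unselected samples only. A static-total variant would
  only rescale all weights within an iteration by a common factor and
  could not change which candidate wins.
* **Normal-sample exclusion.** Samples covered by the selected
  combination are excluded from subsequent iterations — normals included,
  since a normal sample already (wrongly) covered imposes no further cost
  wherever it is counted. Because the alternative reading (only tumors
  are excluded) is defensible, `exclude_covered_normals = FALSE`
  preserves it.
* **Tie-breaking.** Among minimum-weight candidates: larger `TP` first,
  then the lexicographically smallest gene tuple (radix/C ordering, so
  the result is locale- and input-order-independent). Permuting the rows
  or columns of the input matrix leaves the selected set unchanged.
* **Pruning.** Candidates covering no active tumor (`TP = 0`) are
  skipped. This is exact, not an approximation: such a tuple can never
  cover anything in the current or any later iteration.
* **Degenerate inputs.** A cohort with zero tumors yields an empty
  solution. A tumor with fewer than `h` mutated genes can never be
  covered; it is reported in `$uncoverable` and the fit returns a partial
  cover rather than looping. At `alpha = 0` every candidate whose `TN` is
  zero has infinite weight; the greedy step will still select a
  tumor-covering candidate so termination is preserved, while the
  brute-force oracle `exhaustive_best_step()` treats an all-infinite
  slate as "no usable candidate".
* **Gene pre-filtering.** None by default: every gene mutated in at
  least one active tumor enters enumeration. `min_tumor_freq` optionally
  drops genes below a tumor-frequency floor, which can leave tumors
  uncoverable and is therefore off unless asked for.

## Variant filtering and the mutation matrix

Only protein-altering variants count: missense, nonsense/nonstop,
frameshift and in-frame insertions/deletions, and translation-start
changes (`protein_altering_classes()`). Silent, intronic, UTR, flank,
IGR and RNA classes are excluded, as is `Splice_Site` — the set is
protein-centric — but the vocabulary is a plain argument, so
splice-region or multi-nucleotide policies can be changed without
touching code. Matching is case-insensitive; unrecognized terms count as
non-altering.

The mutation matrix is binary presence/absence per (sample, gene):
the cover test is pure set membership, so recurrent mutation of one gene
in one sample carries no extra information here. Coordinates are 1-based
inclusive and chromosome labels are kept verbatim; gene identity is the
raw symbol string with no alias resolution.

## Evaluation protocol

`stratified_split()` partitions tumors and normals independently
(default 75% training), deterministically for a given seed.
A held-out sample is called tumor iff it is covered by at least one
selected combination (`predict()`); `evaluate_cover()` reports
sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and 95% intervals.

The interval method is the **Wilson score interval without continuity
correction** (via `prop.test(correct = FALSE)`). Chosen because, applied
to a published per-cancer-type evaluation row with raw counts 89/101, it
reproduces that row's printed 80–93% interval exactly after integer
half-up rounding — display rounding is half-up to integer percent, with
raw proportions always retained in the machine-readable output. One
caveat is documented deliberately: applying Wilson to the *aggregated*
counts of such a table's total row (1489 of 1632) gives 90–93%, not the
89–92% printed alongside it, so whatever aggregation produced that
overall interval, it was not a Wilson interval of the summed counts.
`aggregate_evals()` therefore sums confusion counts across strata (total-row
semantics) and recomputes a Wilson interval, without claiming parity
with any published total-row interval.

## Post-hoc analyses

* `combination_correlations()` — Pearson r between the 0/1
  mutation-status vectors of the genes inside each combination, computed
  over **normal** samples by default: correlation there suggests a shared
  non-carcinogenic cause (passenger process, structural chromosomal
  event) rather than two independent hits. Pairs with |r| ≥ 0.25 are
  flagged. Per-gene status is the primary reading; a per-position variant
  of the vectors would be a stricter alternative and is intentionally not
  implemented. Zero-variance vectors yield `NA` with a warning — never a
  silent 0.
* `chromosome_colocation()` — flags combinations whose genes share a
  chromosome; many such flags would again hint at a structural artifact.
* `combination_statistics()` — per-combination fraction of tumors
  covered (fractions may sum past 100% since a tumor can carry several
  combinations) and the distribution of combinations per tumor.
* `locus_contrast()` — within samples covered by a combination,
  per-position variant counts in one of its genes, split tumor vs
  normal. Positions mutated in tumors but never in covered normals are
  candidate drivers; positions mutated in both are candidate passengers.
  Positions are genomic `(chromosome, 1-based coordinate)` — a proxy for
  protein residue positions, since consequence annotation is out of
  scope for this package.

## The synthetic cohort generator

`simulate_cohort()` makes the whole pipeline testable without
controlled-access data. Each tumor receives one planted h-gene
combination (all genes set to 1) drawn by the assignment weights, plus a
second distinct one with probability `p_multi`; every sample, tumor and
normal, receives independent per-gene passenger background at rate
`p_background`; normals never receive a planted combination.

Defaults — 60 genes, 5 disjoint planted pairs, 80 tumors, 60 normals,
`p_background = 0.05`, `p_multi = 0.3` — are the package's reference
conditions: cohort sizes in the low hundreds mirror per-cancer-type
cohort scales, a 5% per-gene background gives normals a realistic
handful of mutated genes each (3 of 60 on average), and `p_multi = 0.3`
produces a visible multiple-combination regime without dominating.
Problem sizes throughout the tests (≤ 100 genes, ≤ 200 samples) keep the
full suite in seconds while still exercising multi-iteration fits.

What the generator deliberately does **not** emulate: mutational
signatures or any dependence between genes, hypermutator samples,
subclonal structure, copy-number events, germline variants, and
gene-length effects on passenger probability. Consequently, a passing
pipeline on synthetic cohorts demonstrates algorithmic correctness
(coverage guarantee, per-step greedy optimality, recovery of planted
signal under independent noise) — it does not certify performance on
real tumor cohorts, where passenger structure is far richer.

Two exact-recovery facts the tests rely on: with `p_background = 0` and
disjoint planted pairs the greedy fit returns exactly the planted set
(a planted pair always covers at least as many active tumors as any
cross-pair assembled from two different planted tuples, and strictly
more unless the tuples always co-occur); and any fitted cover classifies
100% of coverable training tumors as tumor, by construction of the loop.

## Numerical choices

* `search_space_size()` returns a double. Binomial sums at genome scale
  (≈ 10²⁹) exceed exact 64-bit integer range; 15 significant digits is
  far more precision than the order-of-magnitude accounting this
  quantity serves.
* Weights are compared exactly (no tolerance): within an iteration all
  candidate weights are computed by the same expression from integer
  counts, so equal-weight ties are exact float ties.
* `write_maf()` assigns each gene a deterministic synthetic chromosome,
  locus and protein-altering classification (by position in the sorted
  gene list), so simulated matrices round-trip bit-exactly through MAF.
  A gene column with no mutated sample has no variant rows to carry it,
  so the round-trip identity holds on the support of the matrix;
  `build_mutation_matrix(genes =)` pins the full universe when needed.
* Both `simulate_cohort()` and `stratified_split()` restore the caller's
  RNG state; reproducibility comes from their explicit `seed` arguments.

## Known limitations

* Exhaustive candidate enumeration limits practical use to `h = 2` at
  genome scale; `h ≥ 3` needs the kind of parallel search this package
  does not attempt.
* The greedy solution is near-optimal, not optimal; different train/test
  partitions can select different, similarly-scoring rare combinations.
* Per-gene binarization cannot distinguish driver from passenger
  mutations within a gene; `locus_contrast()` is the post-hoc aid, not a
  fix.
* No COSMIC/pathway annotation, no variant calling or consequence
  prediction: the package consumes already-called, already-classified
  variants.
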