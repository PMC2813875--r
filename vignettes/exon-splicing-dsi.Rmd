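---
title: "Windowed differential splicing indexes for exon-array data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed differential splicing indexes for exon-array data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exondsi)
```

## The measurement model

An exon array interrogates each exon-sized target with a probeset (PS);
probesets group into transcript clusters (genes) and carry an ordinal
position along the transcription direction. `exondsi` standardizes that
ordering as 0-based, 5'→3', re-densified after sorting, because all of its
splicing statistics are defined on *contiguity* of probesets, not on their
raw ordinal values. Signals are handled throughout on the log2 scale, with
additive Gaussian noise assumed (log-normal multiplicative error on the raw
scale) — the standard error model for microarray intensities.

Two sample groups A and B are compared through the per-probeset difference
of group-mean log2 signals,
$\delta_i = \bar{A}_i - \bar{B}_i$. Uniform (whole-gene) expression
differences make $\delta$ constant; alternative splicing makes it locally
structured. The three differential splicing indexes are zero-sum linear
contrasts over each window of four contiguous probesets
$(\delta_n, \delta_{n+1}, \delta_{n+2}, \delta_{n+3})$:

* **step** — first half vs second half: sensitive to alternative
  first/last exons and exon extensions (a breakpoint in the profile);
* **bump** — inner pair vs outer pair: sensitive to cassette exons and
  retained introns spanning two probesets;
* **spike** — the second probeset vs the mean of the other three:
  sensitive to single-probeset events.

`dsiT(n) = |dsi1| + |dsi2| + |dsi3|` is assigned to the window's anchor
(first) probeset; the last three probesets of each gene carry no complete
window and are unscored. Zero-sum coefficients give two exact guarantees
that the test suite checks property-style: adding any constant to $\delta$
(i.e. shifting one group's whole-gene expression) leaves every index
unchanged, and swapping A and B negates each dsi while preserving dsiT.

Two genuinely open choices had to be fixed. First, the exact coefficient
values: the definition above honors every stated constraint of the method
(three indexes, 4-PS windows, group-mean log signals, absolute values
summed) and the coefficients live in one internal function so they can be
substituted without touching any other code. Second, whether a probeset's
dsiT sums over *all* windows covering it or only its anchored window: the
anchored-window reading was chosen as the simplest deterministic one-score-
per-probeset assignment; a covering-window variant would smooth scores
along the gene but also triple-count strong boundaries.

## Selection and aggregation

Per comparison, the `k = 100` highest-dsiT probesets are flagged, ties
broken by ascending probeset id for determinism. The default comparison
plan mirrors a hematopoietic study design: each of two hematopoietic groups
vs each of 10 solid tissues plus the hematopoietic pair — 21 comparisons,
hence exactly 2,100 selections when every comparison has ≥ 100 scoreable
probesets. A mixed-composition group (spleen, containing both hematopoietic
and solid-tissue cells) is excluded from the plan. Selections count once
per comparison before deduplicating to the candidate AS transcript list, so
a transcript selected in many comparisons carries a higher support count.

Selection is quota-based, not threshold-based: the list always has
(up to) `21 × k` entries regardless of how much true splicing exists. This
is by design — the method ranks candidates for validation — but it means
the false-discovery content of the list depends entirely on how much true
signal is present, which the synthetic null runs in the test suite make
explicit.

## Preprocessing defaults

* **Normalization** — an additive shift on log2 signals equalizing each
  sample's 75th percentile at the median of the per-sample percentiles
  (multiplicative scaling on the raw scale). This is the simplest transform
  that "conserves" a percentile across samples; it preserves within-sample
  rank order exactly and fails loudly on constant-signal samples.
* **DABG filter** — keep a probeset when at least 3 samples (counted over
  all samples jointly, not per group) have detection p ≤ 0.05, boundary
  inclusive. The filter returns a mask; matrices are never silently
  subset. Order of operations is fixed: scale → filter → summarize.
* **Summarization** — median over a cluster's retained probesets per
  sample (mean available). The median was preferred as robust to residual
  splicing structure inside a cluster; the upstream tooling this mirrors
  used an unnamed proprietary summarizer, so the method is parameterized
  rather than guessed.

## Differential expression

`sam_test()` implements the two-class SAM scheme:
$d = (\bar{x}_1 - \bar{x}_2)/(s + s_0)$ with pooled standard error $s$ and
a fudge factor $s_0$ chosen as the percentile of the per-gene standard
errors minimizing the coefficient of variation of the spread of $d$ across
bins of $s$ (a fixed percentile can be forced with `s0_percentile`; at
$s_0 = 0$ and equal variances $d$ reduces to the ordinary two-sample
pooled-variance t form). The null comes from label permutations — 100 by
default, enumerated exhaustively with a warning whenever fewer distinct
assignments exist, which also makes the permutation q-values exactly
invariant to relabeling samples within groups. A gene's q-value is the
median permuted count of $|d^*| \ge |d|$ over the observed count, made
monotone along the $|d|$ ranking; calls require both the fold-change cutoff
(on de-logged group means, default 2) and q ≤ FDR (default 0.05).
Plain label permutations are used rather than "balanced" subsets, which are
only defined for particular blocked designs; for a two-class comparison the
full label-permutation null is the standard choice.

`venn_signatures()` decomposes two up-regulated lists into common and
group-specific signatures by exact set algebra; `overlap_with_de()` counts
AS-list membership in the up- and down-regulated unions.

`fisher_enrichment()` tests over-representation of the AS list against the
expressed background (the genes surviving the DABG filter — the comparison
is AS vs non-AS genes *within* the analyzed set, so expression-dependent
detection bias cancels to first order). Raw two-sided Fisher p-values are
flagged at p ≤ 0.01 and Benjamini–Hochberg adjusted values are reported
alongside, because the raw-p convention is only meaningful for a fixed
annotation release; no gene-ontology release is bundled — categories are
user-supplied (two-column TSV or GMT).

## The synthetic-data generator

`simulate_dataset()` emulates the study design the pipeline targets:

* 13 groups — whole blood (4 samples), CD34+ HSPC (3), 11 solid tissues
  (3 each, one of them the excluded spleen-like mixed group);
* per-gene contiguous probeset series (4–12 probesets), gene baselines
  N(8, 1) log2, probeset affinities N(0, 0.5), noise sd 0.3 log2 — values
  chosen as typical of log2 exon-array signal; the source study reports no
  noise magnitudes, so these are generator defaults stated here, not
  inferred quantities;
* 10% of genes carry a whole-gene ±2 log2 expression difference in one
  random group; a disjoint 10% carry one localized splicing event of a
  random type (cassette, intron retention, alternative first/last exon,
  exon extension) of ±2 log2, planted in one of the two
  hematopoietic-like groups — events in the excluded mixed group would be
  invisible to the default plan by construction, so the generator models
  the lineage-specific splicing the design is meant to find;
* 10% of probesets sit at the noise floor (baseline − 5 log2), tagged with
  the speculative `full` evidence class; expressed probesets are `core`;
* detection p-values are computed analytically as the one-sided Gaussian
  upper tail of signal above the noise floor with sd 1.0 log2 — the
  pipeline needs a filterable p-value, not the array vendor's probe-level
  background model. A signal at the floor maps to p = 0.5; background
  probesets therefore spread around 0.5 and almost never reach p ≤ 0.05,
  while anything ≥ 2 log2 above the floor is detected with high
  probability.

Planted-gene assignment is a seeded shuffle sliced to exact counts, so
truth tables are exactly recoverable and fractions are deterministic.
Event spans never overlap within a gene (one event per gene).

What the generator does *not* emulate: probe-level (25-mer) intensities
and cross-hybridization, correlated probe effects, partial isoform
mixtures (events are all-or-none shifts of group means), batch structure,
and realistic gene-length or expression distributions. Passing recovery
tests on this generator therefore demonstrates the selection logic and the
index's contrast behavior, not field performance on hybridization data.

## Numerical and degenerate-input choices

* Probeset ids are zero-padded so lexicographic tie-breaking equals
  numeric order.
* Clusters with fewer than 4 retained probesets are unscoreable and
  reported via the `excluded` attribute of `group_delta()`.
* All-zero dsiT comparisons still select deterministically (first k by
  id); quotas clip with a warning when fewer probesets are scoreable.
* Readers reject malformed input (duplicate ids, non-numeric cells with
  row/column reported, missing columns by name) rather than coercing;
  writers emit 17-significant-digit text so finite values round-trip
  bit-exactly.
* Stage seeds in `run_pipeline()` are derived deterministically from the
  config seed, keeping every stage independently reproducible.

## Problem sizes

The bundled tests and the acceptance script run on simulations of 300–500
genes (≈ 2,400–4,000 probesets, 40 samples) and 100 label permutations —
sizes at which every stochastic check (planted-event recovery ≥ 80%,
SAM null calls within the FDR bound, 4-fold recovery ≥ 90%) is stable
across seeds while the full suite stays fast. The pipeline itself is
vectorized per comparison and scales linearly in probesets × comparisons.

## Known limitations

The index scores probesets, not isoforms: a selected probeset flags *that
differential exon usage exists near it*, with no deconvolution of which
transcripts produce the signal. Genes shorter than 4 retained probesets
are invisible. The quota-based selection has no significance guarantee —
downstream validation (or the enrichment comparison against the expressed
background) is where inference happens. The dsi coefficient reconstruction
satisfies the method's stated constraints but is configurable precisely
because it is a reconstruction.
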