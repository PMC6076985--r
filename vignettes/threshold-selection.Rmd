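---
title: "Methods: co-occurrence mapping and permutation-null threshold selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence mapping and permutation-null threshold selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `pheno2go`, the
parameters it exposes, and the design decisions a user should understand
before trusting (or changing) the defaults.

## 1. The mapping model

Let an HPO term $h$ be annotated to a set of genes $A_h$ and a GO term $g$
to $A_g$, both drawn from the same gene-symbol namespace. With
$n = |A_h \cap A_g|$, $N_{hpo} = |A_h|$ and $N_{go} = |A_g|$ counted over
each term's *whole corpus*, the co-occurrence similarity is the Dice-style
score

$$S = \frac{2n}{N_{hpo} + N_{go}} \in [0, 1],$$

which reaches 1 exactly when the two terms annotate identical gene sets.
`build_raw_mapping()` emits one record per term pair with $n \ge 1$. Two
quantities drive everything downstream: $S$ (how specific the
co-annotation is) and $n$ (how much evidence supports it). A pair can have
a high $S$ on a single shared gene, which is why both thresholds exist.

## 2. The permutation null

`randomize_annotations()` applies one uniform random bijection to the
entity labels of the phenotype table. Two properties matter:

* every per-term annotation count is preserved *exactly* (a bijection
  neither merges nor splits gene sets), so the null mapping table has the
  same marginal structure as the original;
* the identity coupling between the phenotype and function corpora is
  destroyed, so co-occurrence in the null table is pure chance. For a pair
  with whole-universe counts $N_{hpo}$, $N_{go}$ over $G$ genes, the null
  co-annotation count is hypergeometric with mean $N_{hpo} N_{go} / G$ —
  this is verified against simulation in the acceptance tests.

`build_null_mapping()` repeats the relabeling `n_permutations = 10` times
(seeds `seed + 1 … seed + 10`) and the selection step pools the resulting
null similarity values. A single permutation is adequate on corpora with
millions of annotations, but on desk-scale corpora one relabeling produces
only a handful of chance co-occurrences at $n \ge 2$, starving the test;
pooling stabilizes the null distribution without changing its shape. The
size-capped summaries described next make the comparison insensitive to
the pooling factor (pooling changes sample *size*, which the cap removes,
not sample *location*).

## 3. Threshold selection

For each cell of the grid (similarity thresholds
$S \ge \{0, 0.1, \ldots, 0.6\}$, where the 0 column means $S > 0$, crossed
with count thresholds $n \ge \{1, \ldots, 5\}$ — 35 cells), both tables are
filtered and their $S$ distributions compared with a two-sample
Kolmogorov–Smirnov test. A cell is *significant* when $p < \alpha = 0.01$:
the surviving original mappings are then demonstrably not drawn from the
chance distribution.

The test is not run on the raw $S$ values. Raw-value KS p-values scale
with sample size, so the same degree of divergence would be significant on
a large corpus and insignificant on a small one, and corpus size is an
artifact here, not evidence. Instead each side is reduced to a fixed-size
summary:

1. bin the $S$ values into half-open bins $(lo, hi]$ of width
   `bin_width = 0.02` and replace each value by its bin midpoint (this is
   the "compare histograms, not values" step — it also bounds memory on
   corpora with millions of mappings);
2. take at most `sketch_size = 20` equally spaced order statistics
   (type-1 quantiles at probabilities $(j - \tfrac12)/m$), so the KS
   sample length is $\min(20, \text{records})$.

The cap makes cells comparable across corpus sizes and keeps small planted
corpora in the regime where the $n \ge 1$ cell (dominated by chance
singleton co-occurrences on both sides) is correctly non-significant while
cells that exclude the singleton noise are strongly significant.
`min_records = 3` filtered mappings are required on each side; cells below
that are reported as `insufficient` (`NA` p-value) rather than tested.

**Scan order.** The selection is the *first* significant cell scanning
similarity thresholds in ascending order and, within a similarity
threshold, count thresholds in ascending order. Ascending order implements
"the lowest thresholds at which the data diverge from chance": any higher
cell discards more true mappings for no additional reliability. Similarity
is the outer loop because $S$ is the quantity whose distribution the test
compares; $n$ is the tiebreaker that removes single-gene coincidences.

On the standard planted corpus (1,000 genes, 150 HPO terms, 200 GO terms,
50 planted pairs of 3–6 genes, background rate 0.002) this machinery
selects $(S > 0, n \ge 2)$ across seeds, retains 100% of planted pairs and
removes ≥ 99% of background-only pairs. All of these parameters —
`s_grid`, `n_grid`, `alpha`, `bin_width`, `sketch_size`, `min_records`,
`n_permutations` — are arguments of `select_thresholds()` /
`build_null_mapping()` and can be changed; the defaults above are the ones
the test suite pins.

## 4. Prediction and evaluation

`predict_hpo()` transfers phenotype terms through filtered mappings: a
protein annotated with GO term $g$ receives phenotype term $h$ with score
$S(h, g)$, the maximum over competing GO routes (ties broken by the
lexicographically smallest GO id, for determinism). Scores below
`score_floor = 0.01` (the minimum expressible in the two-decimal exchange
format) are dropped, as are ontology roots.

Evaluation follows the CAFA2 conventions:

* truth and predictions are propagated by the true path rule (`is_a` and
  `part_of` edges) and roots are removed from both sides before
  comparison;
* precision at threshold $\tau$ averages over proteins with at least one
  prediction; recall averages over *all* benchmark proteins in full mode
  (over predicted proteins in partial mode);
* $F_{max}$ is the maximum harmonic mean over the grid
  $\tau \in \{0.01, \ldots, 1\}$; the weighted variant replaces counts
  with summed information accretion
  $ia(v) = -\log_2 \Pr(v \mid \mathrm{parents}(v))$;
* $S_{min} = \min_\tau \sqrt{Ru_\tau^2 + Mi_\tau^2}$, with $Ru$/$Mi$ the
  per-protein mean summed information content of false negatives/false
  positives; the all-predictions-discarded point is always part of the
  scan, so $S_{min}$ never exceeds the empty-prediction distance. The
  per-protein mean (rather than a corpus-level normalization) is a
  documented implementation choice;
* term-centric AUROC uses the rank-average (Mann–Whitney) tie convention
  with missing predictions scored 0; negatives are benchmark proteins
  lacking the term, and terms with no positive or no negative are skipped
  and reported.

## 5. The synthetic generators: scope and limits

`generate_planted_dataset()` plants co-annotation signal — for each
planted (HPO, GO) pair, one shared random gene set of 3–6 genes — on an
independent Bernoulli background (rate 0.002 per gene–term combination).
It reproduces the *regime* the method assumes (sparse corpora where true
signal sits on thin random co-occurrence), not real HPO/GO term-frequency
distributions: real corpora have heavy-tailed term sizes and correlated
annotations (an optional `degree_exponent` adds hub genes, but defaults to
homogeneous). Background annotations landing on planted terms dilute
planted similarities below 1 — under the defaults planted pairs stay above
$S \approx 0.4$ while background pairs concentrate at $n = 1$.

`generate_benchmark_case()` draws a score for every
(benchmark protein, term) pair: positives $s + (1 - s)U$, negatives
$(1 - s)U$ with $U$ uniform. The balanced design is deliberate: at
separability $s = 0$ the two groups are exchangeable and macro AUROC
centers on 0.5; at $s = 1$ negatives fall below the score floor and every
metric reaches its ideal. These anchors calibrate the evaluation machinery
and are checked in the acceptance tests.

## 6. Numerical and reproducibility notes

* All randomness flows through explicit integer seeds via an internal
  scoped-RNG helper that restores the caller's RNG state, so library calls
  never perturb a session's random stream and identical seeds give
  byte-identical outputs (the CLI manifest records the seed and input
  hashes).
* Binning uses half-open $(lo, hi]$ intervals with a $10^{-9}$ guard so
  values equal to a bin edge land deterministically in the lower bin
  despite floating-point division.
* KS p-values come from `stats::ks.test()`, exact for small samples
  (including in the presence of the ties that bin midpoints create) and
  asymptotic otherwise.
* Information accretion uses base-2 logarithms; roots have $ia = 0$; a
  term's conditional probability is estimated against the entities
  annotated with *all* of its parents, and terms with an empty denominator
  are omitted from the result.

## 7. Limitations

* Mapping quality is bounded by annotation quality: evidence-code
  filtering (13 curated codes by default; `IEA` optional) trades corpus
  size against reliability, and the method inherits any ascertainment bias
  in the corpora.
* The KS grid tests marginal $S$ distributions; it does not model
  dependence between term pairs sharing genes.
* The selection returns a single global threshold pair; no per-term or
  per-branch adaptivity.
* Desk-scale fixtures validate properties of the machinery, not
  genome-scale performance numbers, which depend on archived corpus
  snapshots.
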