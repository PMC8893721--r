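---
title: "Signature-reversion drug retrieval: methods and design"
author: "sigreverse maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversion drug retrieval: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreverse)
```

## The problem

Connectivity mapping ranks compounds by how strongly their induced
transcriptional changes *reverse* a disease expression signature: genes up
in disease should be pushed down by the compound, and vice versa. The
reference data are LINCS-style level-5 perturbation profiles — one
moderated z-score per landmark gene per compound treatment in a given cell
line, dose and time stratum — and the query is a disease signature split
into an up-regulated and a down-regulated gene set, optionally with log2
fold-change magnitudes.

`sigreverse` implements the full retrieval workflow: six matching methods,
two benchmarking standards that quantify how well a method's ranking
retrieves genuinely active compounds, the sweep machinery used to choose
operating parameters (trimming depth, query signature size), a multi-level
cosine-similarity analysis of cross-cell-line consistency, and a seeded
synthetic generator so that all of it runs, and is tested, fully offline.

## Matching methods

All six methods score one compound profile against one query signature and
are reported in **lower = stronger reversal** orientation.

The four *eXtreme* methods first apply extreme trimming: only the `topN`
most up- and `topN` most down-regulated genes of the compound profile keep
their values; everything else is set to zero, on the view that small
z-scores are noise. Ties are broken deterministically by gene identifier.

* **XSum**: `sum(profile[up]) - sum(profile[down])` over the trimmed
  profile. A reverser drives disease-up genes negative, so its XSum is
  strongly negative.
* **XCos / XCor / XSpe**: cosine, Pearson, or Spearman correlation between
  the query vector (fold-change magnitudes when available, else ±1) and
  the trimmed profile restricted to the query genes, zeros included. A
  perfect reverser is the negation of the query pattern and scores −1; a
  mimicker scores +1. The correlation is therefore already
  reversal-oriented and is reported as is.
* **KS** and **RGES** use the *complete* (untrimmed) profile, ranked by
  z-score descending. The maximum-deviation (MD) enrichment score of a
  gene set at sorted 1-based positions `V(1..t)` in a list of length `n`
  is

  ```
  a  = max_j ( j/t - V(j)/n )
  b  = max_j ( V(j)/n - (j-1)/t )
  ES = a  if a > b  else  -b
  ```

  with `es_up` and `es_down` the MD scores of the query's two sets. KS
  reports `es_up - es_down` unless the two have the same algebraic sign,
  in which case it is 0; RGES reports `es_up - es_down` unconditionally.
  When `a == b` the `-b` branch is taken, following the original
  connectivity-map statistic.

Numerical notes: the MD statistic satisfies `a >= 0` and `b > 0`, so an ES
is never exactly zero; it is *sign*-antisymmetric but not
magnitude-antisymmetric under profile negation (reversing the list maps
`a' = b - 1/n`, `b' = a + 1/n`), which is why our property tests assert a
sign flip only away from the `|a - b| <= 2/n` boundary. Correlation scores
are marked missing (`NA`) — never silently zero — when a vector has zero
norm or variance, e.g. when every query gene was trimmed away.

`scoreProfiles()` is the batch driver. It ranks each profile once and
reuses the rank matrices across methods and, in `topnSweep()`, across all
trimming depths, which makes full 50–489 sweeps cheap.

## Benchmarking standards

**DR-AUC** asks how well scores separate *effective* compounds
(IC50 < 10 µM) from ineffective ones. Profiles are collapsed to one score
per compound by the median, and the rank-based (Mann-Whitney) AUC of the
classifier "more negative score ⇒ effective" is computed with half-credit
for ties. Higher is better. Significance comes from permuting the labels
(default 10,000 times); the p-value uses add-one smoothing,
`(1 + #[perm >= obs]) / (nPerm + 1)`, so it is never exactly zero, and the
raw fraction is reported alongside.

**DR-ES** asks whether a curated agent set (compounds with independent
evidence of activity) is enriched at the strong-reversal end of the
ranking. Compounds are ranked by score descending and the unweighted MD
enrichment score of the agent set is computed, exactly as in classic
(unweighted) gene-set enrichment; agents concentrated at the
strong-reversal (bottom) end give a negative DR-ES, and no normalised
score is computed. Lower is better. The default permutation null redraws
agent-set *membership* (random compound sets of the same size); permuting
scores instead is available, as is a |score|-weighted ES variant, because
the exact GSEA flavour is a free choice we expose rather than hide.

Two sweeps support parameter selection. `topnSweep()` re-evaluates both
standards at every trimming depth (KS/RGES are computed once — they ignore
trimming), and `binSummarize()` averages over half-open 50-wide topN bins
(the final partial bin is flagged) to damp single-topN outliers before an
operating window is chosen; the default `topN = 200` reflects the
consistently good `[150, 250)` window we observe on synthetic data.
`sizeSweepRandom()` draws random sub-signatures of increasing size (simple
random sampling without replacement, directions preserved; default 1000
replicates per size), and `sizeSweepFc()` builds nested signatures by
iterating the |log2FC| threshold from 0.1 upward in steps of 0.05,
deduplicating identical gene sets.

## Similarity hierarchy (L1–L5)

To quantify how cell-line-specific perturbation responses are, cosine
similarities are aggregated at five levels: L1, same compound measured in
two cell lines (replicate pair combinations averaged); L2, per-compound
median over its cell-line pairs; L3, per-MOA median of member L2 values
(groups below `minMoaSize = 5` compounds are kept in the table but flagged
out of ranked output); L4, per cell-line pair median of same-compound L1
values; L5, per cell line, median of all L1 values from pairs involving
it. All comparisons default to one fixed (dose, time) stratum — 10 µM,
6 h — and crossing strata requires an explicit flag. Two figure-level
ambiguities are exposed as options rather than resolved silently: L4 can
alternatively use *all* cross-cell profile pairs (`l4AllPairs = TRUE`),
and L5 can aggregate pair medians instead of raw L1 values
(`l5From = "l4"`). A hook, `l4BasalCorrelation()`, rank-correlates L4 with
an externally supplied basal-expression similarity table.

## Query-signature construction

`deSignature()` extracts a signature from a two-group log2 expression
matrix using a deliberately simple statistic — per-gene mean-difference
log2FC, Wilcoxon rank-sum p, Benjamini–Hochberg adjustment — with the
strict default cuts adjusted p < 0.01 and |log2FC| > 1 (the relaxed
convention p < 0.01, |log2FC| > 0.5 is a parameter choice away). Model-based
DE fitting is intentionally out of scope; externally derived signatures
can always be supplied as TSV/GMT files.

The *backward* strategy searches signature space directly:
`randomLandmarkSignatures()` draws (by default) 10,000 signatures of 100
genes from the landmark space by simple random sampling without
replacement, and `selectOptimalSignature()` evaluates each with one method
and both standards, returning the candidate minimising
`DR-AUC × DR-ES` — the most negative product combines high retrieval AUC
with strong agent enrichment. Because all six methods need directions but
a random gene draw has none, directions are assigned by an independent
fair coin per gene with a redraw guard so both directions are always
present; a fixed up-fraction rule is available when a specific composition
should be mimicked. Ties are broken by the earliest candidate index, and a
selection in which no candidate reaches a negative product is flagged
rather than hidden.

## The synthetic generator

`simConfig()` / `simulateReference()` emulate a LINCS-like reference set
with a single additive model: the profile of compound *k* in cell line *c*
is

```
s_k * shared_k + (1 - s_k) * specific_kc + N(0, noiseSd^2)
```

with standard-normal shared and cell-specific components. The sharing
coefficient `s_k` (default 0.1, reflecting the weak cross-cell consistency
of real perturbation data) is the single dial behind the similarity
hierarchy: higher sharing raises L1–L5 together, and the noise-free,
full-sharing limit gives exactly 1. A fraction of compounds (default 10%)
are planted *reversers*: they additionally receive `-beta_k × pattern` on
the disease-signature genes in every cell line, with
`beta ~ Unif(0.5, 2)` and the pattern carrying the signed log2FC
magnitudes (drawn Unif(1, 3) per gene, a realistic spread around
|log2FC| = 2 for the default 48-up/22-down signature shape).

`simulateBenchmark()` maps reversal strength to a pseudo-IC50,
`log10(IC50) = 1.5 - 1.5 * beta` plus lognormal jitter, placing
non-reversers near 32 µM (ineffective at the 10 µM threshold) and strong
reversers well below it, and samples the 27-compound agent set with
beta-proportional weights — emulating a curated set of genuinely active
agents; setting the exponent to 0 gives uniform (null) sampling, which is
how the calibration tests break the score–label link. `simulateQuery()`
realises the same planted pattern as a case/control expression matrix so
that signature extraction and size sweeps can be tested end to end; the
pattern is a deterministic function of the config, so reference and query
agree without shared state. All sub-streams derive from one master seed
and identical configs give byte-identical serialised outputs.

What the generator does *not* emulate: dose–response and time kinetics
(the workflows fix one stratum), inference of non-landmark genes, batch
and plate structure, and correlated gene–gene covariance. Passing tests
therefore demonstrate correctness of the statistics and the machinery
around them, not performance claims about any real reference corpus.

## Test and verification sizes

The test suite re-derives every scoring primitive against independent
brute-force oracles (explicit running-sum enumeration for the MD score,
all-pairs concordance for DR-AUC, group-by averages for bin means, all at
1e-12), checks permutation-p calibration under a null generator (200
replicates of 40 compounds with 199 permutations each; the fraction of
p < 0.05 must sit in [0.02, 0.09]), and exercises the planted-signal
conditions at the full default scale (978 × 500 × 9, XSum at topN 200).
These sizes are the package's chosen verification scale; every threshold
in the acceptance tests restates a property of the method, not a tuned
constant.

## Limitations

* Gene identifiers are matched as exact case-sensitive strings; no alias
  resolution is attempted because the intended gene space is a fixed
  landmark set.
* Replicate level-5 profiles surviving the filters are scored
  independently; any aggregation (e.g. the median collapse used by the
  benchmarking standards) is explicit.
* The DE statistic is intentionally minimal; for real cohorts a
  model-based pipeline should produce the signature, which the package
  then consumes.
* GCTX/HDF5 binary matrices are not parsed; GCT 1.2 text is the supported
  interchange format.
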