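---
title: "Consensus prediction and leave-one-out benchmarking of signature-based drug repurposing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus prediction and leave-one-out benchmarking of signature-based drug repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsig)
```

## The model and its assumptions

`drugsig` operationalizes a single hypothesis: compounds whose multitarget
protein-interaction profiles are similar exhibit similar biological effects.
The profile — the *interaction signature* — is a real-valued vector of
predicted compound–protein interaction scores in $[0,1]$ over a fixed
protein library. Nothing in the package assumes the scores come from any
particular upstream predictor; only that higher means "more likely to
interact" and that every compound is scored against the same proteins.

Dissimilarity between signatures is the root mean squared distance
$d(a,b)=\sqrt{\tfrac1P\sum_p (s_{ap}-s_{bp})^2}$. RMSD weights every protein
equally and is insensitive to column order but not to column rescaling;
inputs on wildly different scales per protein should be normalized upstream
(the reader warns on out-of-$[0,1]$ scores rather than failing, precisely to
let such inputs through deliberately).

Prediction for an indication is a *consensus over the similarity lists* of
its associated drugs: a candidate's consensus score counts the associated
drugs to which it is among the `cutoff` most similar compounds. This is
deliberately rank-based, not distance-based — it is robust to the overall
scale of distances and to single outlier drugs — at the cost of discarding
distance magnitude, which only re-enters as the final tiebreaker.

## The total order on candidates

The sort key is (count desc, mean within-cutoff rank asc, mean full-list
rank asc, mean distance asc, compound id asc). The first two keys are the
published two-stage description of the consensus protocol; the next two are
the documented tiebreakers for compounds that never enter a cutoff window.
Two choices here were genuinely open and are resolved as follows:

* **A single global key** rather than two separately sorted segments: for
  count > 0 compounds the extra keys only break residual ties, so the single
  key reproduces the two-stage order exactly while guaranteeing totality.
* **Compound id as the last key**, compared in C-locale (radix) order, makes
  every ranking a deterministic permutation regardless of platform locale.
  The same rule breaks exact distance ties inside the similarity lists
  themselves and site-score ties in the scoring layer.

"Appears above the cutoff" is read inclusively (rank $\le$ cutoff),
consistent with cutoffs being named top-10/25/100. The candidate universe
defaults to the full drug library — published ranks are reported "out of"
the whole library — and `exclude_known = TRUE` restricts to novel compounds
when the goal is prospective prediction rather than benchmarking.

## Benchmarking protocols

The *original* protocol scores list quality only: IA is the percentage of an
indication's drugs whose similarity list contains another associated drug
within the rank cutoff. The *new* protocol assesses the actual product of
the platform, the consensus list: each drug is withheld in turn, re-ranked
from the remaining drugs, and its final rank $r$ summarized as
nIA($k$) $= 100\cdot\Pr[r\le k]$ and nNDCG $= 1/\log_2(r+1)$ (ideal DCG $=1$
for the single-relevant-item case, so DCG and NDCG coincide).

Aggregation follows the nIA → nAIA path: per-association NDCG is averaged
within an indication, then unweighted across indications. The unweighted
mean gives small indications the same voice as large ones; this is a stated
property of the aggregate, not an accident. Indications with fewer than two
associated drugs cannot be assessed by leave-one-out and are skipped and
reported, never silently scored.

Two null models calibrate the metrics. The analytic control for nAIA($k$) is
$100\,k/N$ for $N$ candidates — the hypergeometric single-success case. For
nNDCG no closed form is convenient once ties and consensus structure enter,
so the control is empirical: each protein column of the matrix is
independently permuted across compounds (preserving every protein's marginal
score distribution while destroying all compound structure), the benchmark
is re-run, and 10 replicates are averaged. Column-wise permutation was
chosen over full-matrix shuffling because it keeps per-protein score
distributions — often heavily zero-inflated — intact.

## Interaction scoring (C / CxP / dCxP)

When a matrix is built rather than supplied, the chemical component of a
compound–protein score is the compound's best Tanimoto similarity to any of
the protein's predicted binding-site ligands. `C` uses that alone; `CxP`
multiplies by the confidence score of the site that contributed the best
ligand; `dCxP` first maps the chemical score to its percentile among all
compounds *for that protein*, then multiplies by the site score. Two
ambiguities were resolved and flagged:

* the **percentile axis** (per protein across compounds, not per compound
  across proteins) — chosen so each protein column is calibrated against
  the same compound population;
* the **percentile convention**: fraction of context scores $\le$ the score
  ("weak" percentile), which is bounded in $(0,1]$ and maps the maximum to
  exactly 1.

Proteins with no predicted sites contribute 0, not `NA`, so all signatures
keep full length and RMSD stays well-defined.

## Parameter optimization

`split_mapping()` randomly partitions benchmarkable indications 30/70
(round half up on the indication count) into optimization and evaluation
mappings, whole indications traveling together so no indication contributes
to both tuning and assessment. The split seed is a required, logged
parameter: the published splits of this protocol family are random and
unreproducible, so downstream association counts are treated as
seed-dependent, not as targets. The shuffle is unstratified; stratifying by
indication size was considered and rejected as unstated in the protocol
being emulated.

`sweep_cutoffs()` benchmarks every requested similarity-list cutoff (the
full range runs to the library size; the CLI demo default is 1–100, which is
where all published optima fall) and `find_optimum()` takes the argmax,
ties to the smallest cutoff — preferring the cheaper, more conservative
parameter when performance is flat.

## The synthetic world

`generate_synthetic()` produces the stated world the tests run in: each
indication has an archetype signature drawn from the uniform background;
its drugs are the archetype plus i.i.d. $N(0,\sigma)$ noise clipped to
$[0,1]$; everything else is background. Defaults (50 compounds, 100
proteins, 5 disjoint indications of 4 drugs, $\sigma = 0.05$,
2048-bit fingerprints with 48 on-bits, half shared within a cluster) were
chosen once: the compound/indication scale matches the smallest instance the
acceptance criteria exercise, $\sigma=0.05$ sits well inside the regime
where clusters are tighter than background ($d \approx \sigma\sqrt2 = 0.07$
within clusters versus $\approx 0.41$ between uniform signatures), and the
fingerprint density mirrors typical ECFP4 bit counts for drug-like
molecules.

What the generator emulates: the association structure of a drug–indication
mapping, tunable cluster tightness, chemically clustered fingerprints, and a
site library whose ligands are drawn from the compound fingerprint
population. What it does not emulate: real chemistry (bits are not derived
from molecules), overlapping indications (disjoint by default to keep oracle
expectations clean), zero-inflated interaction-score distributions, and the
"me-too drug" redundancy of approved-drug libraries. A green test therefore
establishes that the machinery recovers planted structure and is calibrated
against its own nulls — not that any particular performance level will hold
on real matrices.

Numerical notes: Gaussian noise is clipped, which biases within-cluster
distances slightly downward near the bounds; the $\sigma\sqrt2$ expectation
is asserted only at small $\sigma$. All randomness flows through one
seed-local RNG so generation never perturbs, and is never perturbed by, the
caller's RNG state.

## Known limitations

* RMSD is the only signature distance; cosine or correlation distances are
  out of scope by design.
* The hypergeometric nAIA control conditions only on $k/N$; if the true
  null conditions on indication size in additional ways, the analytic
  control is an approximation (the empirical permutation control does not
  share this caveat).
* Spearman correlations (`spearman()`, average ranks for ties) require
  non-constant inputs; `correlate_performance()` reports `NA` for saturated
  metrics rather than failing, which on small synthetic worlds happens
  quickly.
* `compare_mappings()` consumes a user-supplied indication match table;
  ontology-based automatic matching is not attempted.
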