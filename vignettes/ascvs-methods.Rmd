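---
title: "Information-theoretic virtual screening with ascvs: models, choices, limits"
author: "ascvs authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic virtual screening with ascvs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ascvs)
```

## The problem

High-throughput screens label a few dozen compounds active among thousands
of inactives.  `ascvs` implements automated system-cognitive (ASC) analysis
for such tables: every molecular descriptor — text pharmacophore codes and
numeric properties alike — is discretized into *gradations*, the training
sample becomes a binary object-by-gradation incidence matrix, and a family
of knowledge models quantifies, per gradation and class, how much evidence
that feature value carries for or against class membership.  Objects are
then recognized by a signed percent similarity to each class profile, and
models are compared by crisp and fuzzy reliability measures.

The method makes no distributional assumptions about descriptors (everything
passes through coding), handles mixed text/numeric inputs uniformly, and its
outputs are directly interpretable: a knowledge matrix cell is "how much
does holding this feature value argue for this class".

## Coding: scales and gradations

A column is treated as numeric only when *every* non-missing value parses as
a number; one stray token makes the column text.  This mirrors a real
failure mode of tabular imports, where a single mis-entered cell (or a
trailing blank line) silently degrades a column, and it is why the reader
skips trailing empty lines.

Numeric columns are partitioned into `numericBins` contiguous intervals,
half-open `[lo, hi)` with the last closed.  The default is
**equal-frequency binning with 3 bins**: screening descriptors such as
molecular weight and polar surface area are heavy-tailed, and equal-width
bins would starve the tails.  Columns with at most `numericBins` distinct
values get one point gradation per value, so a binary blood–brain-barrier
flag yields exactly two gradations.  Text values are whitespace-normalized
(surrounding whitespace stripped, internal runs collapsed) before gradation
matching: a stray space is a data-quality bug, not a new feature value.
Missing values set no incidence bit and therefore contribute zero evidence
in the additive recognition sums — they are not a gradation of their own.

At recognition time, new numeric values outside the trained range clamp to
the boundary interval (with a warning); never-seen text values code as
absent for that scale (with a warning).  Re-coding the training table with
its own scales never triggers either path.

## The frequency substrate and the nine models

All models are functions of the absolute frequency matrix
$N_{ij}$ = number of objects of class $j$ holding gradation $i$, with
margins $N_i$, $N_j$, the grand total $N$, per-class object counts
$N^{obj}_j$, and the probability views
$P1_{ij} = N_{ij}/N_j$, $P2_{ij} = N_{ij}/N^{obj}_j$,
$P1_i = N_i/N$, $P2_i = N_i/N^{obj}$ (0/0 read as 0).

| id | formula | reading |
|----|---------|---------|
| PRC1 | $P1_{ij}$ | conditional percentage distribution |
| PRC2 | $P2_{ij}$ | object-conditional distribution |
| INF1 | $\Psi\log_2(P2_{ij}/P2_i)$ | Kharkevich measure, object base |
| INF2 | $\Psi\log_2(P1_{ij}/P1_i)$ | Kharkevich measure, frequency base |
| INF3 | $N_{ij} - N_iN_j/N$ | chi-square deviation from independence |
| INF4 | $P2_{ij}/P2_i - 1$ | ROI criterion, object base |
| INF5 | $P1_{ij}/P1_i - 1$ | ROI criterion, frequency base |
| INF6 | $P2_{ij} - P2_i$ | probability difference, object base |
| INF7 | $P1_{ij} - P1_i$ | probability difference, frequency base |

$\Psi = 1/\log_2 N^{obj}$ bounds the Kharkevich values near $[-1, 1]$ so
that "units of information" are comparable across datasets.  For the log-
and ratio-based criteria (INF1/2/4/5), cells with $N_{ij}=0$ are set to 0:
absence of co-occurrence is read as *no* knowledge rather than infinitely
negative knowledge, which keeps recognition sums finite.  Under exact
feature–class independence all seven INF models vanish identically; INF3's
rows and columns always sum to zero because its margins cancel.

The assignment of formulas to the ids PRC1–INF7 is this package's fixed
reconstruction of the two probability bases crossed with the Kharkevich,
ROI and difference criteria plus the chi-square deviation; criterion ids
are explicit strings and other systems' internal numberings should not be
assumed to match.

## Recognition

The integral criterion compares an object's binary profile $L$ with a class
column $I_{\cdot j}$ on a signed percent scale:

* **correlation** (default): $S(o,j) = 100\,\mathrm{cor}(I_{\cdot j}, L)$,
  zero when either vector has zero variance.  Bounded, scale-invariant in
  the model column, and effectively a matched filter: gradations with large
  $|I|$ dominate.
* **info_sum**: $100\sum_i I_{ij}L_i / \sum_i |I_{ij}|$ — the additive
  "sum of knowledge" reading.

The predicted class is the top of the descending similarity ranking; ties
break to the first class in classification-scale order and are logged.  A
decision is *positive* for class $j$ when $S(o,j) > 0$; this sign rule
feeds the reliability counting and artifact flagging.

## Reliability: F and the fuzzy L1

Over all object-by-class pairs, positive decisions split into TP/FP and
non-positive ones into FN/TN; $F_1 = 2TP/(2TP+FP+FN)$.  The fuzzy L1
measure replaces each TP/FP/FN count with the decision's similarity
magnitude $|S|/100$, so confident errors cost more than timid ones and
barely-positive hits earn little:
$L_1 = 2TP_f/(2TP_f + FP_f + FN_f)$.  Model selection ranks by L1, with
F1 and then the criterion id breaking ties deterministically.

Two behaviors of these measures under **extreme class imbalance** deserve
explicit documentation, because they bound what values are reachable at a
1.4% active rate:

* The raw-probability models (PRC1/PRC2, and the frequency-base INF2/5/7)
  have columns that correlate positively with *every* typical object — the
  two class profiles share the dominant baseline. Every object then fires
  positively for both classes, so precision is pinned near 1/2 and L1 near
  0.7, whatever the data quality.
* The centered models (INF3 and kin) have anti-symmetric columns in the
  two-class case, so $S(o,\mathrm{Inactive}) = -S(o,\mathrm{Active})$.  A
  typical inactive carries almost no information distinguishing it from the
  baseline — the majority class *is* the baseline — so its own-class
  similarity hovers near zero and roughly half the majority class sits on
  the wrong side of the sign rule by chance.

Consequently, on heavily imbalanced training samples no model reaches L1
near 1 under these definitions; near-unit L1 is reachable only after
cleaning on data whose surviving objects are all sign-consistent (see the
balanced examples in the test suite).  The evaluation is retrospective on
the training sample — the classical ASC protocol — and therefore optimistic;
no cross-validation is attempted, by design.

## Artifact removal

An artifact is a training object whose similarity to its own class falls
below a threshold (default 12, strict `<`, on the signed percent scale).
Two design choices depart from the most literal setup, both for cause:

* **Leave-one-out scoring (default).**  A training object pulls its own
  class profile toward itself; with ~100 objects in the active class this
  self-similarity is worth about +8 points — enough to lift exactly the
  label-noise objects the mechanism exists to catch above the threshold.
  `flagArtifacts()` therefore subtracts the object's own count contribution
  before forming its class column.  On planted-noise simulations this
  raises artifact recall at threshold 12 from roughly 85–92% to ~100%
  without touching genuinely typical objects' ranking.
* **INF3 as the default scoring model.**  Selecting the scorer by L1 on the
  uncleaned sample picks a raw-probability model (see above) that flags
  nothing at any sensible threshold.  The chi-square model is the
  conventional "current model" for heavy recognition work and separates
  label-noise objects sharply; `modelCriterion = "best"` remains available.

Cleaning iterates flag–remove–retrain up to `maxPasses` (default 1) or
until nothing is flagged.  If a pass would empty a class gradation the pass
aborts with a diagnostic and returns the pre-removal state.  On balanced or
moderately imbalanced data this machinery behaves as expected: clean
separable samples are a fixed point, planted label noise is removed, and
post-clean accuracy never falls below pre-clean.  At a 1.4% active rate the
majority class's own-class similarities cluster near zero (previous
section), so threshold-12 cleaning removes most of the majority class or
hits the abort guard; this is an honest property of the similarity
reconstruction on data whose inactive profile is uninformative, and the
package reports rather than hides it.

## Interpretive outputs

* **Information portrait**: one class column ranked by $I_{ij}$ descending,
  partitioned into contributing ($>0$) and hindering ($<0$) feature values.
* **Significance**: per gradation, the population standard deviation of
  $I_{ij}$ across classes — a gradation with identical knowledge in every
  class carries nothing; scales aggregate their gradations by mean.  The
  Pareto curve is the cumulative normalized share of total significance,
  with `paretoCoverage()` interpolating linearly between ranks.  Range and
  max-|I| are deliberate non-choices: the across-class spread is the
  standard operationalization of "degree and direction of influence".
* **Contribution graph**: the bipartite gradation-to-class edge set with
  weight $I_{ij}$ and sign, filtered to the top-$k$ or top-percent edges by
  $|I_{ij}|$ (ties broken by scale, gradation, class order; zero-weight
  edges never emitted), exported as edge-list TSV or Graphviz DOT with
  red/blue encoding the sign and pen width the magnitude.  These are data
  exports, not rendered figures.
* **Imbalance baseline**: `baselineStats(n, nActive)` returns the active
  prevalence and the accuracy of the trivial all-inactive classifier —
  at 3523 objects with 48 actives, 1.4% prevalence and 98.64% trivial
  accuracy (3475 correct).  Any headline accuracy on such a screen must be
  read against this number.

## The synthetic generator

`generateBioassay()` emulates the statistical *shape* of an AID362-like
screen: ~3.5k objects, 1.4% actives, 214 text + 93 numeric descriptors
(one of them a binary BBB-style flag), pharmacophore-code-like column
names, and log-normal numeric descriptors with varying location and spread.
Class association is planted at the gradation level, in spread units:

* numeric: actives are location-shifted by `effectSize` standard deviations,
  realized exactly as the discretized bin-mass shift of the latent normal
  (the top quantile bin is the designated gradation and values are drawn
  within bins), so the pooled distribution stays log-normal and default
  equal-frequency coding recovers the planted bins;
* text: `effectSize` Bernoulli spreads of probability mass move onto one
  designated category in actives, capped at 0.97.

`labelNoiseCount` objects get flipped labels and are recorded as planted
artifacts.  Identical seeds give byte-identical tables (values are
pre-formatted as text in the same CSV dialect the reader parses), and the
caller's RNG stream is left untouched.

What the generator does **not** emulate: real descriptor covariance and
SAR structure.  Uninformative descriptors are class-independent by
construction, so the inactive class has no profile of its own beyond the
baseline.  Passing tests therefore demonstrate correct mechanics and
parameter recovery under known truth — they do not certify performance on
real screens, where hundreds of correlated descriptors give both classes
informative profiles and similarity distributions are broader.

## Numerical choices

0/0 ratios read as 0 throughout; similarities clip to $[\pm 100]$ against
floating-point overshoot; INF3's conservation is asserted to $10^{-9}$;
frequency fingerprints use a dependency-free FNV-1a hash of the counts;
gradations are 1-indexed in reports and labels, with interval labels
`[lo,hi)` and the final `[lo,hi]`.  Class gradations are ordered by sorted
label, and that order is the documented tie-break everywhere.

## Problem sizes in the test suite

The suite exercises the full AID362 shape (3523 objects, 307 scales) for
the end-to-end checks and smaller configurations elsewhere: brute-force
model equivalence on ≤6-object samples across 25 seeds, prevalence
calibration over 120 seeds at n = 600, and balanced 400-object screens for
cleaning behavior — sizes chosen so each property is tested in the regime
it speaks to while the whole suite stays fast.

## Known limitations

* The criterion-id-to-formula mapping and both integral criteria are
  reconstructions; other ASC implementations need not match numerically.
* The fuzzy L1 form (|S|/100-weighted pair pooling) is one of several
  possible readings of similarity-weighted F-measures; its ceiling under
  extreme imbalance is documented above.  The count-normalized L2 variant
  is out of scope.
* Retrospective evaluation on the training sample overstates real
  performance; treat reported accuracies as internal consistency checks.
* No descriptor computation, standardization, or retrieval: descriptor
  tables arrive precomputed.
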