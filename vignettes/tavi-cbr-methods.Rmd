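---
title: "Methods: hierarchical case-based retrieval for TAVI planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical case-based retrieval for TAVI planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tavicbr)
```

## The problem

Planning a transcatheter aortic valve implantation (TAVI) involves two
linked choices: the vascular access route (right or left trans-femoral,
left trans-subclavian, trans-aortic, trans-apical) and the prosthesis,
treated here as one joint type + size decision (Edwards Sapien XT 23/26,
Medtronic CoreValve 26/29) so that incoherent type/size combinations can
never be proposed. `tavicbr` supports these decisions by case-based
reasoning: a new patient (the *candidate case*) is compared with a
case-base of previously treated patients, the most similar past cases are
*retrieved*, and their confirmed solutions are *reused* through a weighted
vote. The clinician stays in charge of the revise/retain steps; the
package only appends or removes solved cases.

A case carries three groups of fields: the problem description (a mixed
vector of quantitative, ordinal and binary clinical attributes), one
solution label per decision, and outcome fields. Everything is
schema-driven: attribute kinds, ranges, ordinal category lists and the
decision vocabularies live in a YAML config, so hospital-specific
attribute sets plug in without code changes.

## Per-attribute distances

The heterogeneous distance dispatches on the attribute kind:

* quantitative: `|v1 - v2| / range_a`, clipped to `[0, 1]`;
* binary (`yes`/`no`): Hamming, 0 or 1;
* ordinal: a lookup in an expert distance matrix;
* either value missing: the neutral constant **0.5**, for every kind.

`range_a` is **frozen from the initial case-base** — the schema bounds
when declared, otherwise the observed min/max — and deliberately not
recomputed after case filtering or retention. Recomputing it per surviving
subset would make the same attribute difference change value across
retrieval levels; freezing keeps distances comparable, at the cost that a
candidate outside the historical range clips to distance 1 (a degenerate
frozen range, min = max, degrades to exact-match). Distances are kept in
double precision; nothing is rounded before presentation.

Ordinal grades do not influence a decision linearly — an artery with no
calcification is clinically close to a mildly calcified one (distance
0.15), while `No` vs `Heavy` is nearly maximal (0.90) — so the grade-pair
distances are an expert elicitation, not a function of category indices.
Only the calcification matrix is fixed by expertise here; for other
ordinal attributes (e.g. tortuosity, graded on four levels) the default
maps the calcification profile onto the target category count by bilinear
interpolation of normalised grade positions, then restores the zero
diagonal and symmetry. This is a neutral default, not expert knowledge:
any attribute can (and in production should) override it with its own
config matrix, validated on load for symmetry, zero diagonal and
unit-interval bounds.

## Composite measures

Three case-level measures are implemented behind one dispatch:

* **Weighted heterogeneous dissimilarity** — the normalised weighted mean
  `sum(w_a d_a) / sum(w_a)` over a selected attribute set, using the
  dispatch above (missing values count 0.5). Its complement is the
  similarity.
* **HEOM** — the unweighted baseline: the square root of the sum of
  squared per-attribute distances over *all* schema attributes, overlap
  (0/1) for every qualitative attribute (ordinal grades compared
  nominally), range-normalised difference for quantitative ones, and
  distance 1 for a missing value. No selection, no weighting.
* **GWHSM** — a weighted mean with Euclidean/Hamming per-attribute
  distances in which any attribute missing on either side is discarded
  from numerator and denominator alike; a pair sharing no informative
  attribute is an error in the scalar operation and ranks at the maximal
  dissimilarity 1 inside vectorised retrieval, where erroring would abort
  a whole evaluation for one degenerate pair.

The three measures intentionally disagree on ordinal data: one grade step
costs 0.2 under the expert calcification matrix but a full 1 under
GWHSM's exact-match rule — this gap is one reason attribute-aware
measures retrieve better neighbours.

## The clinical decision tree and hierarchical retrieval

Clinical reasoning is hierarchical: for the access decision the
ilio-femoral minimal diameters are examined first, vessel quality
(tortuosity, calcification, prior aneurysm/thrombus) second, patient
build last. A clinical decision tree (CDT) encodes exactly this ordering
— levels of attribute names, each attribute at one level — and drives the
hierarchical measure three ways:

1. *Attribute selection*: at level `l` the dissimilarity uses all
   attributes of levels `1..l`.
2. *Weighting*: an attribute at level `l_a` of an `L`-level tree weighs
   `(L - l_a + 1) / L` — 1 at the root, `1/L` at the deepest level,
   strictly decreasing with depth.
3. *Case selection*: after each level except the last, if
   `m / 2^l > 20` (with `m` the size of the initial case-base), only the
   most similar half of the surviving cases is kept.

The final ranking is by the level-`L` dissimilarity over the last
surviving set; the hierarchical similarity is its complement. Three
details the algorithm statement leaves open are fixed as follows:

* the halving guard uses the *original* `m`, not the current survivor
  count, so the filtering schedule is decided by the case-base size
  alone;
* an odd survivor count keeps `ceiling(count / 2)` cases — retaining
  more evidence and staying deterministic;
* ties, both at the halving cut and in the final ranking, are resolved by
  `(dissimilarity, case id)` stable order, and cases past the cut are
  dropped even when tied with the last survivor. A tie at the cut
  boundary is therefore a documented deviation risk against any
  implementation that keeps all tied cases.

The floor of 20 cases means case-bases of up to 40 cases are never
filtered; the hierarchy then acts purely through attribute accumulation
and level weights. The default trees shipped in `inst/extdata/` are
reconstructions of the clinical ordering described above and are meant to
be overridden per centre — the tree is used only for levelling, weighting
and filtering, never executed as an if/then rule engine.

## Reuse: the weighted vote

The k retrieved cases vote for their solutions with weight
`(k + 1 - rank) / diss`, and the suggested solution is the argmax; scores
are also normalised to percentages that sum to 100, the confidence shown
to the user. Two situations the vote rule leaves open are engine
decisions: an exact duplicate has dissimilarity 0, so the divisor is
clamped below at `eps = 1e-9`, keeping the score finite while letting the
duplicate dominate as it should; and exact score ties are broken
lexicographically by label, which is arbitrary but deterministic and
auditable. Scores scale as `1/c` when all dissimilarities scale by `c`,
so the winner and the confidences are scale-invariant.

## GA weight learning for the GWHSM baseline

The GWHSM baseline learns attribute weights with a genetic algorithm: a
floating-point chromosome per weight vector, fitness = the leave-one-out
precision of 1-NN retrieval under those weights (each case removed in
turn, its nearest neighbour's solution compared with the confirmed one).
Crossover rate 0.75, per-gene mutation rate 0.20, 300 generations,
roulette-wheel parent selection and elitist carry-over of the top 30% are
the reference configuration and the defaults. Choices the configuration
leaves unspecified: population size 50; weight bounds `[0, 1]`;
whole-arithmetic crossover with a uniform blend coefficient and Gaussian
per-gene mutation (sd 0.1, clipped to bounds), both standard operators
for real-valued chromosomes; and roulette selection falls back to uniform
when the whole population has fitness zero. Elitism makes the
best-of-generation fitness non-decreasing by construction, which the
tests assert. Because the fitness depends on weights only through
weighted sums of fixed pairwise per-attribute distances, those distances
are precomputed once per run, making a fitness evaluation a handful of
matrix sums.

## Evaluation designs

Two designs are provided: leave-one-out cross validation (each case
retrieved against the remaining `m - 1`, frozen ranges kept from the full
base) and holdout (every test case against the full training base, e.g.
real cases as training set and generated cases as test set). Both report:

* the **retrieve-based criterion** — the confirmed solution appears among
  the k retrieved cases (monotone in k by definition);
* the **reuse-based criterion** — the vote suggests the confirmed
  solution (never exceeding the retrieve rate at equal k, since the vote
  chooses among retrieved solutions);
* one-vs-rest **sensitivity and specificity per solution** from the 1-NN
  prediction, with empty denominators reported as absent rather than
  zero;
* a TPR/FPR summary. The multiclass convention is not canonical, so it is
  isolated in one function and documented: TPR is the micro-averaged 1-NN
  accuracy, FPR the macro average of one-vs-rest false-positive rates
  over the labels present in the test set.

The k sweep in examples is kept at or below roughly 10% of the training
set size; beyond that the retrieved set stops being a meaningful shortlist
for a user.

## Synthetic data

Two generators make every module testable without patient data.

The **TAVI profile** emulates the structure of a real registry extract:
joint (access, prosthesis) labels drawn from mixtures in which the
trans-femoral routes together exceed 80%, as in practice, and each
attribute drawn around a label-conditional centre — femoral calibre,
tortuosity, calcification and prior disease determined by the access
route, annulus dimensions and valve area by the prosthesis, demographics
label-free. In *separable* mode the relative noise is 0.2% and
ordinal/binary values sit exactly at their class centre, so every joint
class forms a tight cluster separated from all others by at least one
attribute gap more than ten times the within-class spread; nearest
neighbour retrieval then recovers the labels perfectly under all three
measures, and any realised singleton joint class is reassigned to the
majority class so leave-one-out retrieval has a same-class neighbour to
find. *Noisy* mode (8% relative noise, 30% ordinal drift, 10% binary
flips) produces overlapping classes for rate-comparison tests. What the
generator does **not** emulate: correlations among demographics (BMI is
drawn, not derived from weight and height), missing values, operator
variability in ordinal grading, and any real patient distribution — so
perfect scores on separable data validate the machinery, not clinical
performance, and the reference study's headline sensitivities cannot be
reproduced from synthetic data alone; with a real case-base CSV and
centre-specific CDT/matrix configs the same harness emits those tables
deterministically.

The **planted profile** serves the weight-recovery study: a two-label
decision determined entirely by one quantitative `signal` attribute plus
three pure-noise attributes. The class centres are deliberately close
(0.47 vs 0.53, against within-class noise of about 0.002): the signal
alone still classifies perfectly, but equally weighted retrieval errs on
roughly a third of cases. That gap is what makes weighting identifiable —
with widely separated centres the noise attributes would be harmless,
every weighting would score 1, and no learner could be distinguished from
chance.

**Augmentation** doubles a case-base with label-preserving generated
cases: quantitative attributes jittered multiplicatively within ±10% and
clipped to the schema interval, ordinal grades moved at most one step
(uniform over down/same/up), binary values, solutions and results
untouched, and measurement attributes tied to a solution resampled inside
the solution-consistent interval (the shipped IFU-style annulus ranges per
prosthesis — synthetic stand-in values, editable in
`inst/extdata/ifu_ranges.yaml`). The jitter distribution is uniform; per-
label histograms are exactly doubled by construction.

## Problem sizes and numerical choices in the test suite

The suite validates the composite dissimilarity against a literal
independently coded transcription on 200 random mixed-type schemas/case
pairs, and hierarchical retrieval against a brute-force transcription
(explicit loops, re-sorting each level) on random case-bases of up to 32
cases and trees of up to 3 levels, both to 1e-12; the filtering branch is
exercised by lowering the floor parameter. Rate-level checks use
separable case-bases of 40–60 cases, the GA recovery study 10 seeded runs
at population 30 and 50 generations on 60-case planted bases, and the
filtering trace a 138-case noisy base. The full suite runs in well under
a minute on one CPU.

## Known limitations

* The default CDTs and non-calcification ordinal matrices are neutral
  reconstructions, not elicited expertise; results on real data hinge on
  replacing them with centre-specific configs.
* The tie policy at the halving cut (drop beyond the cut even when tied)
  is one of several defensible readings of "keep half".
* GWHSM's maximal-distance fallback for pairs with no shared informative
  attribute is a ranking convenience; heavily missing data deserves a
  real missing-data strategy.
* The multiclass TPR/FPR convention is a documented choice; compare runs
  only under the same convention.
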