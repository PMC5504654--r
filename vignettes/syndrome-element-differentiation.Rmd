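---
title: "Syndrome-element differentiation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Syndrome-element differentiation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedq)
```

This vignette documents the model implemented by `sedq`, the parameters
that matter, the numerical conventions adopted at the edges, and what the
synthetic-data generator does and does not emulate.

## The scoring model

Inquiry diagnosis asks a fixed questionnaire (177 questions for male
respondents, 194 for female; questions 1–177 are shared) and records one of
four answer levels per question, fusing severity and frequency:
A (severe/always) → 1, B (a little severe/sometimes) → 0.618,
C (not severe/seldom) → 0.382, D (none/never) → 0. The golden-ratio-spaced
weights make one severe answer worth roughly a severe-ish and a mild answer
together; they are fixed constants of the method, not tunable.

The knowledge base is a mapping-weight matrix: rows are questions, columns
the 47 syndrome elements, and a positive entry in (0, 100) states how
strongly that symptom indicates that element; zero means no mapping. A
record's element value is the inner product of its answer-weight vector
with the matrix column — an unnormalised weighted sum. We deliberately do
not normalise: value orders (below) are ratios within a differentiation
group, so any global scaling cancels, and keeping raw sums preserves
additivity over question subsets (a property the test suite checks).

Two health states can be scored. The *overall* state uses all answers; the
*major* state keeps only severe answers. "Severe" defaults to level A
alone; level B can be admitted via `severity_filter("severe_only",
c("A","B"))`. A record with no severe answer carries no major-state signal
and is flagged by `batch_quantify()`; evaluation drops such records rather
than scoring vacuous all-zero vectors, so a severe-mode report covers only
the records with severe symptoms.

Elements 7 (Deficiency) and 8 (Excess) are composite eight-principle
judgements that are not computed from answers in this framework; how a
deployed system derives them is outside our scope. They stay in the
registry (indices must remain stable) but are excluded from value-order
assignment and matched-degree evaluation, leaving 45 evaluable elements in
groups of 6, 7, 16 and 16.

## Value orders

Within each group, let `max` be the largest value among its evaluable
elements. Each element with value `v > 0` gets order
`[0.95,1]→8, [0.9,0.95)→7, [0.85,0.9)→6, [0.8,0.85)→5, [0.6,0.8)→4,
[0.4,0.6)→3, [0.2,0.4)→2, (0,0.2)→1` on `r = v/max`, and order 0 at
`v = 0` (the rule table has no row for ratio 0; absence is its own rank).
A wholly zero group assigns order 0 throughout. Bands are left-closed, so a
ratio of exactly 0.2 is order 2. Orders are scale-invariant by construction,
and every non-degenerate group contains an order-8 element (its maximum).

## Weight condensation

Four rules condense original weights onto a small ordinal scale intended to
carry qualitative meaning (10 ≈ strongly indicative … 2 ≈ weakly
indicative):

* **Symptom basis** quantizes the weight value directly.
* **Element basis** first divides each weight by the maximum of its element
  column (computed over the whole matrix, not per record), then quantizes
  the ratio. Every mapped column therefore contains at least one condensed
  weight of 10.
* **Normal** granularity uses four bands; **fuzzy** granularity inserts
  secondary weights (8, 5, 3) near band boundaries, realised entirely by
  the explicit secondary intervals of the rule tables — no additional
  "closeness" heuristic is applied, because the tables already enumerate
  the secondary ranges.

The interval brackets are taken literally, including their quirks: under
the fuzzy value rule, a weight of exactly 10 falls in (8, 10] → 3, not in
(10, 12); under the fuzzy ratio rule, a ratio of exactly 0.2 falls in
(0.15, 0.2] → 3. One genuine defect exists in the printed normal value
table: the bands [10, 25) → 4 and (0, 10] → 2 both contain exactly 10. We
resolve it in favour of the left-closed band (10 → 4), which matches the
table's dominant left-closed convention and keeps the quantizer monotone
non-decreasing — the property that guarantees condensation never inverts
the qualitative trend of weights within a symptom row or element column.
Values at or above 100 and ratios outside (0, 1] are domain errors, not
clamped: the value scale is defined as the open interval (0, 100).

Sex-specific matrices are condensed independently; the rule object carries
no sex.

## Matched-degree evaluation

With the original-weight value orders as standard, a condensed matrix is
scored per record and group as `MDG = (CG − Σ SE_W)/CG`, summing `SE_W`
over elements whose order differs between the two assignments, and
integrated as `MD = Σ MDG·CG/CT` with `CT = 45`. Mismatch is a 0/1
indicator on order equality, not a graded distance. The mismatch weight
`SE_W` is, by default, the order weight of the element's *reference*
(original-standard) order: the standard defines how much a disagreement
matters. This is the principal interpretive choice in the formula — the
source defines `SE_W` only as "the weight of syndrome element" — so
`group_matched_degree()` exposes `se_w_source = "reference" | "test" |
"max"`. Two order-0 elements compare as consistent (absence matching
absence is agreement), which also gives a wholly zero group MDG = 1
vacuously.

`MDG` and `MD` always lie in [0, 1]; `MD = 1` iff all four group degrees
are 1. Cohort distributions are binned on the percent scale as
[95,100], [90,95), …, [60,65), [0,60) — left-closed with a doubly closed
top bin, one fixed bin set for every group and for the integrated degree.

## Knowledge discovery (APOSD)

Step 1 extracts, per record, the elements whose value order is at the
record's highest attained level — the per-record maximum, not globally
order 8, so every retained record contributes at least one attribute; ties
are all included, and records whose orders are all zero are dropped with a
warning. Step 2 takes records as objects and those top elements as
attributes of a formal context. Step 3 grows the layered diagram by a
recursive greedy maximal-coverage partition: at each node, the attribute
covering the most objects not yet consumed by earlier siblings is selected;
objects possessing it descend, the rest are re-partitioned as siblings; an
object terminates when its attributes are exhausted. This construction is
our reconstruction of the published diagram semantics ("the innermost layer
covers the most objects"), which the original algorithm literature defines
elsewhere; the test suite pins it against an independently coded
realization and against direct support counting. Equal-coverage ties are
broken by ascending element index, for determinism. The result is a tree
(equal branches are not merged into a DAG); each object lies on exactly one
root-to-leaf path whose attribute set is exactly the object's intent.

`extract_combinations(tree, depth, min_support)` reports root-to-node
chains of exactly `depth` layers with all supports at least `min_support`.
Exactly-`depth` (rather than up-to-`depth`) matches how frequent
combinations are conventionally tabulated as uniform-length chains;
shallower branches can be read off at a smaller `depth`. Rendering is left
to DOT consumers; `export_diagram()` emits deterministic DOT and JSON, the
latter round-tripping losslessly.

## Synthetic data

Neither a clinical cohort nor a curated mapping matrix is distributable, so
`generate_matrix()` and `generate_cohort()` emulate their statistical
shape, and every default below is a modelling choice made once, not a
measured value:

* **Matrix**: 194 questions (177 male-applicable), 2–6 mapped elements per
  question with weights uniform on (0.5, 99.5), every evaluable element
  reachable, columns 7/8 empty. Real matrices are curated, not uniform:
  their weights cluster, which *raises* matched degrees after condensation
  (nearby weights quantize identically). Synthetic results therefore
  under-state, not over-state, condensation agreement.
* **Cohort**: sex ratio 301/670 male; answers i.i.d. with
  P(A, B, C, D) = (0.009, 0.06, 0.15, 0.781). The A-probability is set so
  that about 80% of records contain at least one severe answer over a
  177-question form, mirroring the severe-record fraction typical of a
  general screening cohort; the overall symptom sparsity reflects that most
  inquiry questions are not applicable to any one person. Inquiry time is
  Gaussian (mean 900 s, sd 300 s, truncated at 0) purely so screening has
  something to act on. No clinical symptom co-occurrence is modelled: the
  simulator validates pipeline mechanics and statistics, and passing tests
  say nothing about diagnostic accuracy on real patients.
* **Screening** excludes (a) records with no symptom (all answered D),
  (b) records faster than a caller-supplied minimum inquiry time — the
  "normal standard" is deployment-specific, so `min_inquiry_seconds` has
  deliberately no default — and (c) records with all answers identical,
  tested in that order so an all-D record is tagged (a) and an all-A record
  (c). Kept and excluded records always partition the input.

All generators are seeded and restore the caller's RNG state.

## Problem sizes and determinism

The shipped tests run the complete workflow at cohort scale — 670 records,
the full 194-question questionnaire, all four condensation rules — plus
1000-instance quantification oracles and 100 random-context APOSD oracles;
the whole suite completes in about a minute on a single core, quantification
being two matrix products per rule. Byte-identical reports under identical
configuration, and manifest checksums that move iff an input or parameter
moves, are asserted in the pipeline tests.

## Known limitations

* Elements 7 and 8 are carried but never scored; systems that derive them
  need to plug in their own rule.
* The matched-degree statistic compares order labels only; two assignments
  differing by one order level everywhere score the same as wildly
  divergent ones with equal mismatch counts and reference weights.
* The APOSD greedy partition is order-sensitive only through its
  deterministic tie-break; it is a reconstruction of the layered-diagram
  semantics, not a transcription of the originally published algorithm.
* Condensation thresholds are fixed tables; learning them from data is out
  of scope.
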