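---
title: "mirCascade: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirCascade: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirCascade)
```

## The problem

Epigenetic inhibitors of lysine demethylases (for example the dual
LSD1/UTX inhibitor MC3324) reshape the miRNome of hormone-dependent breast
cancer cells, and some of the modulated miRNAs feed back on ERα signaling.
`mirCascade` implements the inference cascade that nominates such
candidate regulators from four independent data layers: (1) qPCR miRNome
profiling quantified by the −ΔΔCt method, (2) multi-tool miRNA target
prediction reduced to a consensus set, (3) transcriptome fold changes used
as an anti-correlation filter, and (4) ERα/LSD1 immunoprecipitation
interactomes used as a protein-level overlay. A fifth module analyses a
paired tumor/normal patient cohort stratified by immunohistochemistry
(IHC).

No single layer is trusted on its own; a miRNA is nominated only when the
layers converge: it is differentially expressed, its consensus targets
move in the opposite direction in the transcriptome, and those targets
surface as treatment-responsive interactors of both baits.

## Relative quantification model

For each assay and condition, replicate CT values are averaged **on the CT
scale** before any subtraction (standard −ΔΔCt practice). Then

* ΔCt(assay, condition) = mean CT(assay) − reference term;
* ΔΔCt = ΔCt(treated) − ΔCt(control);
* relative quantity RQ = 2^−ΔΔCt.

Two reference terms are supported. `reference` subtracts the mean CT of a
designated reference-assay set (e.g. the RNU6B small nuclear RNA), the
appropriate mode for targeted validation qPCR. `global_mean` (the default)
subtracts the per-sample mean CT over all in-bounds assays, the usual
normalization for profiling panels that designate no reference; it is
robust when effects are roughly balanced between directions but is
contaminated when one strongly shifted assay dominates a very small panel
— which is why the validation-qPCR examples in the package use
`reference` mode.

Detection uses the inclusive bounds 16 ≤ CT ≤ 37 (cycles). A missing CT is
out-of-bounds, never imputed. Under the default `all_replicates` rule an
assay is expressed in a condition only if every replicate is in-bounds
(`majority` is available). The two per-condition flags classify each assay
as `common`, `control_only`, `treated_only` or `undetected`; these four
classes always partition the panel, and the first three form the Venn
decomposition.

Direction calls use the inclusive two-fold rule: up iff RQ ≥ 2, down iff
RQ ≤ 0.5. We read the published "2^−ΔΔCT ≥ ±2" criterion this way because
it is the only reading under which the up and down classes are
complementary, and we use the same inclusive rule for every ratio in the
package (tumor/normal ratios, treatment-response folds) for internal
consistency.

## Consensus targets: HIT and observed/expected

A (miRNA, gene) pair's HIT is the number of distinct prediction tools
reporting it, plus exactly one if the pair carries validated-interaction
evidence (one hit regardless of how many databases validate it).
Duplicates within a tool count once; identifiers are matched exactly after
whitespace stripping, with no alias resolution.

The aggregation criterion retains a pair iff HIT ≥ 4 **and** its
observed/expected ratio is ≥ 2, both inclusive and conjunctive. The O/E
null is not published by the aggregation service, so the package declares
one: under tool independence the expected support for any pair of a given
miRNA is

E(miRNA) = Σ_t n_t(miRNA) / N_universe,

where n_t is how many genes tool *t* predicts for that miRNA and
N_universe the size of the gene universe. O/E = HIT / E, with E floored at
1e−9 (logged) to avoid division by zero. This is the simplest pair-level
null consistent with an "observed/expected" criterion; it is isolated in
`oeRatios()` so an alternative (gene- or pathway-level) definition can be
swapped without touching the filter.

## Integration, overlay and ranking

`matchAnticorrelated()` keeps only strict anti-correlation: a
down-regulated gene is *confirmed* when at least one retained consensus
pair links it to an up-regulated miRNA, and symmetrically. Concordant
annotations are dropped (with a logged count); the confirmed-down and
confirmed-up sets are provably disjoint.

`overlayInteractome()` intersects, per bait, the under-represented
interactors with the confirmed-down genes and the over-represented
interactors with the confirmed-up genes. Records exist at 6 h and 24 h;
the published analysis compares against a 24 h transcriptome, so the
package reconciles timepoints with the `concordant` default: a (bait,
gene) whose 6 h and 24 h calls disagree is excluded (logged), otherwise
the call is the consistent one with 6 h retained as annotation. The
alternative `use24` rule always takes the 24 h call. The data we worked
from do not state how discordance was handled, so the rule is explicit and
configurable rather than silent.

`rankCandidates()` scores each annotated miRNA by the number of *shared*
(both-bait, down-regulated) interactors it targets, breaking ties by
membership in a curated ERα-signaling miRNA set, then in a curated
ESR1-targeting set, then lexicographically. The curated sets are inputs,
never inferred: the published ESR1 annotations are not internally
consistent between the correspondence table and the narrative, so
hard-coding either would bake in a contradiction. A count-based score is
used instead of a strict all-rows intersection because the published trio
of convergent miRNAs is itself not the strict intersection of the
correspondence table rows.

## Enrichment

Term-level annotation of confirmed gene lists uses classical
over-representation analysis: the hypergeometric upper tail P(X ≥ k) for
overlap k between a query of size n and a set of size K in a universe of
N genes, with Benjamini–Hochberg adjustment (via `stats::p.adjust`).
Ranked GSEA with permutation nulls is deliberately out of scope; ORA is
the discrete analogue appropriate for fixed gene lists.

## Cohort module

IHC classification follows the standard rules: ER/PR positive at ≥ 1%
stained nuclei (ASCO/CAP), PR "high" and Ki67 "high" at ≥ 20%, HER2
positive only at score 3+ (0/1+/2+ negative, no reflex ISH). The response
grouping is ER-driven: `ER_positive` iff ER-positive, everything else —
including triple-negative and HER2-positive/ER-negative tumors —
`ER_negative`.

The group contrast statistic is declared (the source never defines it):

D = (mean fold ER+ − mean fold ER−) / (mean fold ER−) × 100,

where fold = treated/control expression per (patient, tissue). D is
antisymmetric under group swap via D′ = −D/(1 + D/100) and invariant under
global rescaling of the measurements. The formula is isolated in
`groupResponseContrast()` so median-based or per-patient-log alternatives
can be substituted.

The packaged cohort table transcribes the printed clinical annotations of
the 18-patient cohort. Per-patient ER and Ki67 percentages were published
only graphically; the table therefore carries the published ER grouping
(patients 4, 7, 8, 13, 14 negative) plus a synthetic placeholder `er_pct`
(80/0) consistent with it, as its filename and documentation state;
`ki67_pct` is `NA`. The printed PR value "<5" (PT15) is carried as 4 —
any value in (1, 5) yields the same receptor classes.

## What the generator emulates — and what it does not

`simulateStudy()` reproduces the statistical structure of the study at
desk scale: 300 panel miRNAs with 40 up / 40 down planted effects
(|ΔΔCt| uniform in [1.5, 3]) plus condition-specific assays; Gaussian CT
noise (default σ = 0.2 cycles, additive on the cycle scale); seven
prediction tools at sensitivity 0.8 and per-pair false-positive rate
0.001 over a 2000-gene universe; anti-correlated transcriptome effects at
strength 0.9; a two-bait interactome in which the targets of one
designated convergent miRNA are under-represented for both baits with
single-bait decoys; and an 18-patient cohort with 13 ER-positive / 5
ER-negative patients, baseline tumor/normal ratios 0.25 (15 patients) and
4 (3 patients), and group-mean response folds 1.73 vs 1.00 (tumor) and
1.38 vs 1.00 (normal). Cohort noise is multiplicative log-normal
(positivity-preserving; draws use meanlog = log m − σ²/2 so planted group
means are unbiased), CT noise is additive Gaussian — the standard qPCR
error models.

The generators are fully deterministic under a seed. What they do *not*
emulate: amplification-curve artifacts and probe-specific efficiency,
correlated tool errors (real prediction tools share seed-match logic, so
their errors are positively correlated and real consensus filtering is
weaker than the independent-tool simulation suggests), compositional
coupling between miRNAs, batch structure, and biological heterogeneity of
patients beyond the planted group means. Passing planted-recovery tests
therefore demonstrates correctness of the inference logic, not expected
performance on real panels.

Problem sizes were chosen so that the full suite and the reproduction
script each run in well under a minute of compute per invocation (the
default simulated study takes about a second end-to-end); full
study-scale pair counts can be reached by raising
`nGenes`/`targetsPerMirna`.

## Numerical and degenerate-input choices

* All thresholds are inclusive; ties never fall in a gap between classes.
* Missing CT values are dropped from averages; an assay with no finite CT
  in a condition gets ΔCt = NA, never 0. A sample with no usable
  reference CT in `reference` mode is a configuration error naming the
  sample.
* O/E expectations are floored at 1e−9 with a logged message; a pair with
  HIT 0 has O/E 0, while querying an unknown pair is an error.
* Sorting is always deterministic (DE by |log2 RQ| with lexicographic
  tie-break; consensus and overlay tables by identifier), so reruns are
  byte-identical.
* Validated-only pairs (never predicted by any tool) still carry one hit;
  their expectation uses the same floor.

## Known limitations

The O/E null and the group-contrast statistic are declared stand-ins for
procedures the source does not specify; both are isolated behind single
functions. The ranking resolves the final candidate only through the
caller-supplied curated sets. The cohort module performs no hypothesis
testing on the 15/18 proportion, and no survival analysis. Identifier
harmonisation (miRBase versions, gene aliases) is the caller's
responsibility.
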