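---
title: "System-profile druggability analysis of kinase targets: methods"
author: "dtprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{System-profile druggability analysis of kinase targets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtprofiler)
```

## The question this package addresses

Protein kinases are among the most productive classes of drug targets,
yet most approved kinase drugs treat cancer, and many more kinases sit in
clinical trials than in pharmacopoeias. A recurring idea in target
assessment is that *system profiles* of a protein — how many similar
human proteins exist outside its own family, how many signaling pathways
it participates in, how many tissues express it — carry information about
druggability: a target with few close relatives, few pathway memberships
and narrow tissue distribution is less likely to produce off-target or
on-target-wrong-tissue toxicity. This package implements, as reusable
tested code, a comparative analysis of established (approved-drug) versus
clinical-trial kinase targets built on four components:

1. **Sequence similarity with E-value statistics** — local alignment of
   target sequences against the established-target set, summarized as
   best-hit expectation values and classified into three similarity
   levels.
2. **System profiles and compliance rules** — the per-target triple
   (NS, NP, NT) with threshold rules, cohort summaries and a
   median-trend comparison across development stages.
3. **A combinational druggability rule** — a target is called
   *promising* when it resembles established targets in at least 3 of 4
   profiles (sequence, binding-domain fold, physicochemical, system),
   evaluated retrospectively against tabulated development outcomes.
4. **Bipartite drug–target networks** — degree analysis, popular-target
   identification and ICD disease-class subnetworks with
   Cytoscape-compatible export.

Because the original curated target lists and the database versions
behind them are not published, the analyses run on synthetic data from a
first-class generator module; the one fully reproducible piece of real
data — the 16-row development-status table of previously identified
promising phase-3 targets — ships with the package as a plain-text
fixture (`phase3_status_table()`).

## Alignment statistics

`smith_waterman()` computes the exact maximum-scoring local alignment
under a substitution matrix and affine gap penalties (Gotoh recurrences,
score only; the per-cohort comparisons need scores and lengths, not
tracebacks). Defaults are BLAST-like: BLOSUM62, gap open 11, gap extend
1, so a gap of length $L$ costs $11 + L$.

Raw scores are converted to expectation values with Karlin–Altschul
statistics,

$$E = K\,m\,n\,e^{-\lambda S},$$

where $m,n$ are the sequence lengths and $\lambda$ solves
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ over the background residue
frequencies $p_i$ (Robinson–Robinson values by default). Choices worth
stating explicitly:

* $\lambda$ and $K$ are the **ungapped** parameters of the scoring
  matrix. Estimating gapped parameters requires large-scale simulation
  and is deliberately out of scope; the consequence is that E-values for
  gapped alignments are mildly conservative relative to BLAST's gapped
  statistics. For the classification task here (three broad similarity
  classes) this distinction is immaterial.
* $\lambda$ is found by `uniroot` to relative tolerance $10^{-12}$ after
  bracketing; the function is convex with $f(0)=0$ and $f'(0)<0$, so the
  positive root is unique whenever the matrix has a positive entry and
  negative expected score (both are validated).
* $K$ uses the standard lattice series approximation: with score span
  $d$ (gcd of attainable scores) and relative entropy $H$,
  $K = d\lambda e^{-2\sigma}/(H(1-e^{-\lambda d}))$ with $\sigma$
  accumulated over $k$-fold convolutions of the pair-score distribution
  until terms fall below $10^{-10}$ (at most 120 terms). For BLOSUM62
  with the default background this yields $\lambda = 0.3176$,
  $K = 0.134$, $H = 0.401$, matching the constants printed by standard
  ungapped BLASTP to three figures.
* Effective lengths are the raw lengths; no length correction is
  applied. At the sequence lengths used here (tens to a few hundred
  residues) edge corrections change E by factors well inside one
  similarity class.

Similarity levels follow the three-class convention: *very similar*
($E \le 0.001$), *marginally similar* ($0.001 < E \le 0.1$), *unsimilar*
($E > 0.1$); boundaries are inclusive on the smaller class, matching the
"$\le$" notation in which the classes are conventionally stated. A
target's similarity to the established cohort is its **best hit**: the
minimum E-value over all established sequences.

The NS statistic counts proteome entries from *other* families with
$E \le$ a cutoff. The cutoff is not standardized anywhere we know of; the
package defaults to 0.001, the very-similar bound, for internal
consistency with the classification, and exposes it in the configuration.

## Synthetic cohorts and what they do (not) emulate

Per-target NS/NP/NT values for the real cohorts were never published, so
cohorts are generated from parametric count distributions (negative
binomial by default; Poisson and point mass available).
`cohort_presets()` fixes one calibration, chosen once:

| cohort | NS (mu, size) | NP (mu, size) | NT (mu, size) |
|---|---|---|---|
| established | 8.0, 3 | 2.67, 4 | 1.2, 6 |
| phase3 | 8.5, 3 | 3.0, 4 | 1.45, 6 |
| phase2 | 8.7, 3 | 4.0, 4 | 2.2, 6 |
| phase1 | 10.8, 3 | 2.05, 4 | 2.7, 6 |
| nonclinical | 16.0, 3 | 5.0, 4 | 4.0, 6 |

The calibration satisfies two constraints. First, compliance rates at
the rule thresholds sit near the rates reported for real kinase cohorts
(e.g. established NS compliance 88%, NT compliance essentially 100%,
phase-2 NP compliance 50%). Second, population medians ascend from
established through phases 3, 2, 1 for NS (7, 7, 8, 9) and NT
(1, 1, 2, 2), while NP rises and then dips at phase 1 (2, 3, 3, 2, with
the phase-2 CDF sitting exactly at 0.5 on the threshold) —
the characteristic trend-with-violation pattern the `median_trend()`
checker is designed to flag. The reported per-phase NP compliance
percentages (83/50/82) are mutually inconsistent with an ascending
established→phase3 NP median under any single monotone
negative-binomial family — a higher CDF at the threshold forces a lower
median — so the presets favor the ordinal median structure and accept an
approximate phase-3 NP rate (65%). This is a deliberate package-level
calibration decision.

Two caveats on interpretation. Integer-valued counts make **sample**
medians sit on half-integer lattice points; when a population CDF passes
almost exactly through 0.5 at an integer (by construction, phase-2 NP
does), the sample median of even large cohorts alternates between
adjacent lattice values. The trend scripts therefore report medians
rather than asserting their order, and the trend *checker* is validated
on constructed median sequences. Second, the generator draws NS, NP and
NT independently, whereas in real targets they are correlated (hub
proteins tend to score high on all three); passing recovery tests on
synthetic cohorts shows the estimators are correct, not that real kinase
cohorts look like this.

Sequence families are generated by point mutation of a random seed
sequence at rate $1-\text{identity}$ (mutated positions redrawn from the
other 19 residues), with independent families. Under the default uniform
residue frequencies the expected between-family identity is the
coincidence rate $\sum_i p_i^2 = 0.05$, which makes the cross-family NS
oracle analytic. Real protein families share domain architecture and
compositional bias that this deliberately does not model.

Bipartite networks with prescribed degrees are built by
`realize_bipartite()`: sides are checked with the Gale–Ryser condition,
then a greedy construction connects each drug, in descending degree
order, to the targets of largest remaining capacity, ties broken
lexicographically — fully deterministic, so the printed degree
histograms (46 approved drugs / 25 targets; the 13-drug / 9-target
C51–C58 subnetwork) realize to byte-identical fixtures. Only the degree
histograms of the real networks are printed anywhere, so the fixture is
*a* realization of the published degree sequences, not the true wiring;
every statistic computed from it (node counts, degree histograms,
popularity thresholds, multitarget counts) depends only on the degree
multisets. The target-side histogram is transcribed literally, including
the absence of a degree-8 class.

## Compliance rules, summaries and the promising rule

The rules are `NS < 15` (strict), `NP <= 3`, `NT <= 5`, evaluated on
distinct pathway/tissue counts; duplicate annotation rows count once.
Targets absent from an annotation table count 0 with a warning by
default, because silently changing the denominator is worse than an
explicit policy; exclusion is available. Histogram bins default to
boundaries aligned with the rule thresholds (NS in fives to 20 then
open; NP and NT one-wide through the threshold then open). Boxplot
statistics use Tukey 1.5 IQR whiskers as in base R's `boxplot.stats`.

Report-style percentages are truncated toward zero (37.5 prints as 37):
that is the convention under which the published
5-of-16 = 31% / 6-of-16 = 37% arithmetic is exactly reproduced; raw
values are retained for computation.

`parse_status()` maps free-text development-status strings to outcome
labels with case-insensitive whole-word keywords and precedence
approved > positive > negative/discontinued > other. Two interpretive
choices matter: precedence (a row reporting a positive trial *and* later
approval counts once, as approved), and the whole-word rule, under which
"filed for FDA approval" does not count as approved — both are required
to reproduce the 5/6/5 split of the packaged 16-row table.
`is_promising()` is the 3-of-4 threshold on the A/B/C/D profile flags;
B (structural fold) and C (physicochemical) are *inputs* supplied by a
stub file provider, since their definitions live in prior work outside
this package's scope.

## Networks

`build_network()` enforces strict bipartiteness, referential integrity
(dangling ids are listed), uniqueness of drug–target pairs, and closed
vocabularies for modality and interaction mode. Degree is the undirected
edge count, ignoring activation/inhibition sign. ICD filtering matches
on the 3-character category (C54.1 matches C51–C58) because disease
classes are ranges of categories; subnetworks are induced subgraphs and
drop targets left without a drug, mirroring how disease-class
subnetworks are conventionally displayed. Exports: SIF, GraphML (with
class/modality/stage/cohort node attributes and the mode edge
attribute) and plain attribute TSVs.

## Problem sizes and verification

The test suite validates the alignment engine against two independent
routes: exhaustive enumeration (best globally aligned substring pair,
written as a separate recursion) on all pairs from pools of sequences of
length up to 8, and Biostrings' `pairwiseAlignment` on random pairs up
to length 60. The lambda solver is checked against a hand-written
bisection and the closed form $\lambda = \ln 3$ for the +1/−1 uniform
four-letter scheme. Statistical recovery uses cohorts of n = 2000 with
3-standard-error tolerances; structural invariants (degree handshake,
induced subgraphs, realization fidelity) run over 1000 random bipartite
graphs. The demo pipeline (14 targets, 90-residue sequences) runs in
about a second; these sizes were chosen so the whole suite exercises
every code path in well under a minute while keeping Monte Carlo
tolerances tight enough to catch off-by-one errors at the rule
boundaries (a misplaced `<=` shifts a compliance percentage by several
standard errors).

## Known limitations

* Ungapped E-value parameters applied to gapped alignments (above).
* The synthetic generator draws profile statistics independently and
  sequences from i.i.d. residue models; neither matches real proteome
  structure.
* The promising-rule evaluation is retrospective over a 16-row table;
  the package makes no attempt to re-derive the underlying per-phase
  identification rates, whose target lists were never published.
* Subnetwork fixtures realize degree sequences, not the true published
  wiring (which exists only as figures).
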