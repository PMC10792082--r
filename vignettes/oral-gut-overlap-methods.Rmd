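---
title: "Methods: paired oral-gut species overlap and marker-gene strain consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired oral-gut species overlap and marker-gene strain consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralgut)
```

## The question and the method

Roughly 10^11 oral bacteria are swallowed daily, yet gastric acid, bile,
mucosal immunity and colonization resistance stand between the mouth and the
colon. Whether swallowed oral strains actually colonize the distal gut — or
whether the species seen in both niches are separate pools of niche-adapted
strains — matters clinically, because ectopic gut colonization by oral taxa
(e.g. *Haemophilus parainfluenzae*, *Veillonella parvula*) has been linked to
intestinal inflammation.

`oralgut` implements a two-level analysis of paired, within-subject stool and
oral shotgun metagenomic profiles:

1. **Species level.** For each oral site (saliva, buccal mucosa,
   supragingival plaque, tongue dorsum) paired with stool from the same
   individual, compute each species' *pairwise overlap frequency* — the
   fraction of pairs in which the species is detected in both members — and
   compare its fecal versus oral relative abundance with a paired Wilcoxon
   signed-rank test, Benjamini–Hochberg corrected across the overlapping
   species of that site.

2. **Strain level (marker genes).** Species-level overlap cannot distinguish
   same-strain colonization from niche-adapted sibling strains. Clade-specific
   marker genes can, partially: strains of one species gain and lose markers,
   so the binary presence/absence profile of a species' marker set acts as a
   coarse strain fingerprint. Within each individual, a stool sample whose
   marker pattern is *identical* to an oral sample's pattern for the same
   species is called **consistent with** same-strain colonization. Identity of
   patterns is necessary but not sufficient (SNP-level variation within
   markers is invisible to presence/absence), so the method can overestimate,
   never underestimate, strain sharing.

## Filters and their rationale

* **Prevalence filter.** Before any statistics, species detected in fewer
  than `max(3, ceiling(0.10 * N))` of the `N` samples under assessment are
  dropped. The two-part rule reads "occurred at least 3 times in at least 10%
  of the samples" as a count floor that dominates in small datasets and a
  fraction floor that dominates for `N > 30`. Detection means relative
  abundance strictly above `presence_threshold` (default 0 — the upstream
  profiler already applied a reads-per-kilobase presence floor, so no second
  floor is imposed). The `ceiling` is computed with a `1e-9` slack so binary
  floating-point noise cannot turn `0.10 * 100 = 10` into a threshold of 11.

* **Overlap threshold.** A species is *overlapping* when its pairwise overlap
  frequency is at least 10% of pairs; the boundary is inclusive, so 1 of 10
  pairs qualifies.

* **Marker coverage filter.** Only samples carrying at least 90% (inclusive)
  of a species' full marker set enter the strain comparison. Low coverage
  indicates insufficient sequencing depth — missing markers would then
  reflect missed detection rather than genuine gene loss, and exact pattern
  matching would be meaningless. The coverage denominator is the species'
  complete marker set as given in the marker map.

All three boundaries are monotone by construction: raising the detection
threshold can only lower overlap frequencies, tightening prevalence can only
shrink the retained set, lowering `coverage_min` can only enlarge the
eligible set. The test suite checks these properties on randomized inputs.

## The paired Wilcoxon test

Abundances of one species across pairs are compared with the signed-rank
procedure: zero differences are dropped, tied absolute differences get
midranks, and the two-sided p-value is `P(|W - mu| >= |w_obs - mu|)` under
random signs. For effective `n <= 25` this tail is computed exactly by
dynamic programming over doubled midranks (doubling makes midranks integers,
so the full null distribution is a small convolution) — including in the
presence of ties, where the textbook exact tables do not apply. For larger
`n` the standard normal approximation with tie correction and continuity
correction takes over. A species whose fecal and oral values are identical in
every pair has no defined test; it is flagged (`test_defined = FALSE`) and
reported as non-significant rather than erroring the pipeline. BH adjustment
is performed per oral-site dataset — each site's overlapping-species list is
one testing family, matching how each site's comparison panel is reported.

The niche of origin is inferred from the significant comparisons:
significantly higher oral median → `oral` origin (the typical pattern for
*Streptococcus* and *Veillonella* overlappers, whose fecal medians are
trace); significantly higher fecal median → `fecal` origin (the pattern of
abundant gut commensals detected at trace levels in oral samples);
otherwise `indeterminate`.

## Pairing rule

Samples are paired within `(subject_id, visit)`: timestamps are not part of
the interchange tables, so the visit index stands in for the "collected
within 24 hours" proximity used when the cohorts were assembled. When a
subject has several stool (or oral) samples at one visit, the
lexicographically smallest `sample_id` is used — an arbitrary but
deterministic tie-break, so pairing is reproducible and invariant to input
row order. How multi-visit subjects should be collapsed into pair counts is
genuinely open; one pair per visit is the reading implemented here, and the
pair table makes the choice auditable.

## The synthetic cohort generator

Because the analysis is meaningful only on paired cohorts with known ground
truth, the package ships a seeded generator (`sim_config()`,
`generate_cohort()`) rather than fixture files.

**Community model.** Species belong to three pools: oral-adapted (present in
oral samples with probability 0.8, spilling into stool with probability 0.1),
gut-adapted (present in stool with probability 0.8, never oral), and
generalists (0.8 on both sides) which hold the five frequently overlapping
oral-flora species — *S. parasanguinis*, *H. parainfluenzae*,
*S. salivarius*, *S. mitis*, *V. parvula* — used for strain comparison.
Present species receive independent log-normal magnitudes
(`mu = 0, sigma = 2`, a standard heavy-tailed model for relative-abundance
data) renormalized to sum to 100 per sample. Non-gut-adapted species
appearing in stool draw their magnitudes with the log-mean shifted down by 4
log units, a fixed model constant: oral spillover into feces occurs at trace
abundance, which is precisely what makes the oral-origin inference pattern
(frequent detection, tiny fecal median, `q < 0.05`) reproducible in
simulation. In the vanishingly rare event that no species is drawn present in
a sample, one admissible species is forced present so renormalization is
defined.

**Strain model.** A strain repertoire starts from the species' all-present
marker set (100 markers by default) and loses each marker independently with
probability `gene_loss_prob = 0.02`; draws losing more than 10% are rejected
so that a noise-free strain always passes the coverage filter, and colliding
draws are redrawn so distinct strains differ in at least one marker (with
`gene_loss_prob = 0` and two strains requested, collision is unavoidable and
the generator raises an error rather than looping forever). Exactly
`n_shared_subjects` subjects (default 7) are planted with an identical
stool/oral repertoire for one randomly chosen shared species and site; every
other within-subject (sample, species) combination carries its own distinct
repertoire. Marker detection then fails independently per present marker with
`marker_dropout_prob` (default 0.01); absent markers are never falsely
detected, because clade-specific markers are unique by construction. This
one-sided noise model keeps the noise-free limit exact: with zero dropout,
pattern identity holds if and only if the pair was planted, so the caller
must recover the ground truth perfectly — a property the tests verify across
seeds.

**Default scale.** 125 subjects with all four oral sites give 500
stool/oral pairs, the scale of the multi-cohort data the generator emulates.

**What the generator does not emulate.** Real cohorts have heterogeneous
per-species occupancies and abundances, correlated species (co-occurrence,
competition), compositional structure beyond renormalization, multi-visit
subjects, read-level noise, and contamination. Occupancies here are uniform
within a pool, so simulated overlap-frequency distributions are more
homogeneous than real panels. Passing tests therefore demonstrate the
*correctness of the statistical machinery and the caller* under a controlled
model — not that real oral-gut overlap is large or small.

**Dropout and sensitivity.** Under nonzero dropout, a planted pair matches
only if every shared marker survives (or is lost) on both sides, so the
exact-identity caller's sensitivity decays quickly with
`marker_dropout_prob` — at the default 1% dropout only a fraction of the
planted subjects are typically recovered. This conservatism is inherent to
exact pattern matching and mirrors the asymmetry of the method itself: it may
overcall "same strain" for SNP-divergent strains, but imperfect marker
detection only ever loses true matches. Sensitivity is a nonincreasing
function of dropout (tested over a dropout grid), and the coverage filter
guarantees no call is based on an under-covered sample.

## Numerical and degenerate-input choices

* Inclusive boundaries (`>= 10%` overlap, `>= 90%` coverage) carry a `1e-9`
  slack against floating-point quotients such as `27/30`.
* Equal overlap frequencies order lexicographically; pairing ties break to
  the smallest `sample_id`; all outputs are sorted so repeated runs are
  byte-identical.
* An empty marker-value file is allowed (with a warning): a cohort without
  marker data can still run the species-level analysis.
* Bray–Curtis is undefined for two all-zero vectors and errors explicitly;
  per-site distance matrices are computed on raw relative abundances via the
  manhattan/row-sum identity, while heatmap shading uses
  `log10(x + pseudocount)` with the pseudocount set to the smallest nonzero
  abundance in the table. Ordination (NMDS) of the distance matrix is
  deliberately delegated to standard implementations and is not part of this
  package's computations; the distance matrix and deterministic sample
  ordering are.

## Problem sizes used in the shipped checks

The package's own verification uses desk-scale simulations chosen to make
the properties sharp: oracle comparisons over 1,000 random p-vectors and
1,000 random abundance-vector pairs plus 200 exhaustive sign-flip
enumerations (effective `n <= 10`); exact planted-truth recovery over 20
seeds at 50 subjects with 5 planted sharers and zero dropout; and
overlap-frequency calibration at 500 pairs against planted joint occupancies
of 0.1, 0.5 and 0.9 over 100 seeds each, requiring the estimate inside the
central 99% binomial acceptance region in at least 95% of seeds.

## Known limitations

* Exact pattern identity is a coarse strain proxy: SNP-divergent strains
  with identical marker repertoires are indistinguishable (overcalling), and
  any marker dropout destroys identity (undercalling). Calls are therefore
  labelled "consistent with" same-strain colonization, never "same strain".
* The Wilcoxon variant (paired vs. unpaired) and the prevalence-filter
  pooling are analysis choices exposed in `analysis_config()`; defaults
  follow the paired design of the data.
* Relative abundances are compositional; no CLR or zero-inflation modelling
  is attempted, matching the descriptive intent of the analysis.
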