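---
title: "Methods: dual-arm systems pharmacology and NMR metabonomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-arm systems pharmacology and NMR metabonomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmetab)
```

# The analysis

`pharmetab` implements a two-arm strategy for dissecting how a multi-herb
preparation acts on a disease model, worked here on the bundled case study of
a ten-herb formula given to rats with hydrocortisone-induced kidney-yang
deficiency:

* **Pharmacology arm.** Herbal compounds are screened by four ADME
  descriptors, the survivors' predicted protein targets are filtered by
  pharmacophore-match rank and Z-score, and the retained targets are
  annotated to pathways.
* **Metabonomics arm.** One-dimensional ^1^H CPMG serum spectra are
  calibrated, bucketed, total-sum normalized, modelled by PCA and OPLS-DA,
  and mined for biomarkers by correlation loadings; biomarkers feed a
  MetPA-style over-representation analysis with topology impact.
* **Integration.** The two pathway name sets are intersected after
  canonicalization, and each overlapping pathway is traced back to its
  proteins, compounds and herbs as a typed network.

# Pharmacology arm

## ADME screen

A compound is active when all four comparisons hold: oral bioavailability
OB ≥ 30 %, blood–brain-barrier index BBB > 0.3, drug-likeness DL ≥ 0.18 and
half-life HL ≥ 4 h. Only the BBB bound is strict; this asymmetry follows how
the thresholds are conventionally stated, and comparisons are exact
floating-point comparisons with no epsilon, so boundary records behave
predictably. A record with a missing descriptor is rejected with a recorded
reason rather than raising an error, because upstream property tables are
routinely incomplete. A literature whitelist — taurine and betaine for
Chinese angelica, six cinnamon-bark volatiles — bypasses the screen for
compounds known to be pharmacologically relevant despite poor descriptor
values; `defaultWhitelist()` ships these entries and users can extend the
table. Compounds listed under several herbs are merged into one record with
a herb set, so a shared compound is one node of the herb–compound network
with degree equal to its herb count. Both the union count and the per-herb
counts are reported, since a compound shared by *k* herbs contributes *k*
to the per-herb totals but 1 to the union.

## Target filter and pathway annotation

Target hits are filtered per compound: rank ≤ 300 within that compound's own
ranked list and Z ≥ 0.8, both inclusive. The per-compound reading of
"top 300" follows from per-compound query submission to a pharmacophore
server; it is configurable. Proteins are deduplicated before annotation;
the number of supporting compounds per protein is kept and later used as
network multiplicity, never as a filter. Pathway annotation is a membership
scan of a file-based pathway library plus a literature-mined list of free-text
pathway names, canonicalized identically to library names; entries found both
ways are merged and tagged with both origins.

# Metabonomics arm

## Preprocessing

Spectra are referenced to the lactate doublet: the two highest local maxima
within ±0.1 ppm of δ 1.33 are taken as the doublet lines and the axis is
shifted so their midpoint lands on 1.33. Buckets of 0.004 ppm tile
[0.5, 8.5) left-closed, anchored at the low edge (the anchor side is
configurable since either convention is defensible); a bucket whose interval
intersects the residual-water window δ 4.7–5.2 is dropped whole, which avoids
partial-bucket area bias at the exclusion boundary and leaves 1875 buckets
under the defaults. Bucket values are trapezoidal integrals on the native
grid — no resampling, so the total integral is preserved exactly. Each
sample's bucket vector is divided by its own total; the raw totals are kept
in the object for audit. Total-sum normalization removes per-sample dilution
exactly and is why the synthetic generator's noise model makes dilution
multiplicative.

## OPLS-DA

The two-class model codes classes 0/1 and centers them. On the scaled matrix
the predictive weight is the class-covariance direction
w ∝ Xᵀy; for each orthogonal component the X-loading of the current
predictive score is stripped of its projection on w, normalized, and the
corresponding component is deflated from X. The final predictive component
is fitted on the deflated matrix, which makes the predictive score
orthogonal to every orthogonal score by construction (validated to 1e-8).
Defaults: unit-variance scaling with mean-centering (the common SIMCA-style
default; Pareto is offered because it is the NMR-community norm, and the
choice is stored in the model object), one orthogonal component, and 7-fold
cross-validation with a seeded shuffle and round-robin fold assignment.
Q² = 1 − PRESS/SS over held-out class predictions with SS the total centered
sum of squares. Component signs follow a fixed convention
(largest-|loading| element positive) so repeated runs agree.

At very small sample sizes the permutation null of Q² is not reliably
negative: with 8 + 8 samples a small positive Q² arises in roughly a fifth
of label permutations — with this implementation and equally with an
independent PLS cross-validation — because the chance correlation between
held-out predictions and the permuted labels scales as 1/√n. The permutation
property suite therefore characterizes the null at n = 40 and p = 100, where
the behaviour is stable; users permuting 8 + 8 designs should expect
occasional small positive null Q² values and not over-read them.

## Biomarker selection

Per bucket, r is the Pearson correlation between the predictive score and
the (scaled) bucket, and the plot height is the covariance back-scaled to
original units. The selection threshold is the two-tailed critical |r| at
the chosen n: r* = t*/√(t*² + n − 2). Following the case study's convention
the pipeline quotes the threshold at the per-group size (n = 8 → 0.707)
rather than at the total number of fitted spectra. Buckets are lifted to
metabolites by annotation windows centred on the dominant multiplet lines
(weak outer triplet/quartet lines are not annotated, matching how assignment
shifts are quoted); a metabolite is called when more than half of its
annotated buckets pass, which protects against a single contaminated bucket
— resonances 0.01 ppm apart, such as methionine 2.13 next to glutamate 2.14,
genuinely bleed into each other's buckets. Selected buckets covered by no
annotation are reported as "unassigned" rather than dropped. Both supervised
contrasts (model vs control, treated vs model) are mined and the union of
called metabolites forms the pathway query, mirroring the case study's
18-query panel.

## Univariate statistics

Per metabolite a one-way ANOVA across the three groups, then the two pairwise
contrasts as pooled-variance t tests (Welch offered as an option), Bonferroni
adjusted over the most conservative family — all metabolites × both
contrasts, since the study does not state its family size. Direction is the
sign of the mean difference, reported only when the adjusted p is
significant.

## Enrichment

Over-representation uses the upper-tail hypergeometric probability
P(X ≥ hits) with the universe defaulting to the number of distinct compounds
in the loaded library, the convention of reference-library tools; it is
configurable because printed p-values from such tools depend on their
unprinted universe. −log(p) is the natural log, verified against the bundled
result table (whose row 10 prints a −log(p) inconsistent with its own p and
is treated as a typo). Topology impact sums betweenness centralities of the
matched compounds, normalized so importances over the pathway sum to one, on
an undirected simple graph — edge direction is not modelled because the
library format carries plain edge lists. Rows are ranked by raw p with ties
broken by name for determinism; selection cutoffs are raw p < 0.05 and
impact > 0.1, with no multiplicity adjustment by design.

# Integration

Free-text pathway names from different sources disagree in case, punctuation
and the "/" vs "or" idiom; `canonicalizeName()` case-folds, maps "/" to
" or ", strips punctuation except hyphens (so stereo-prefixes like "d-"
survive) and collapses whitespace. The significant metabonomics pathways are
partitioned by membership in the pharmacology set; overlapping pathways keep
exactly the proteins annotated to them, the compounds hitting a kept protein
and the herbs containing a kept compound. Degrees are computed on the induced
subgraph only, matching how such networks are drawn. Exports are SIF and
GraphML, both consumable by Cytoscape, and the GraphML round-trips.

# The synthetic-data generator

No raw inputs of the case study are public, so the generator is first-class
code producing every input with known ground truth:

* **Compound tables** with planted actives that pass all four thresholds
  while every other compound is forced below at least one.
* **Target hits** giving every planted active at least one passing hit, plus
  sub-threshold decoys.
* **A pathway library** in which the planted overlap pathways contain both
  the actives' target proteins and the KEGG identifiers of the planted
  discriminative metabolites, while background pathways contain neither, so
  the end-to-end integration must return exactly the planted names.
* **Serum-like spectra**: Lorentzian multiplets (FWHM 0.003 ppm ≈ 1.5 Hz at
  500 MHz; unresolved multiplets slightly broadened) at the bundled panel's
  shifts, group concentrations from the panel's directions at a default
  2-fold change (the study reports directions and significance only, so the
  effect size is a free parameter), a stable broad macromolecule envelope, a
  smooth per-sample baseline, a residual-water hump confined to δ 4.7–5.2
  with 10× the largest metabolite peak, a per-spectrum log-normal dilution
  factor (CV 0.1) and an additive noise floor. All stochastic components
  scale with `noise_cv`, so 0 gives deterministic spectra; all randomness
  flows from the single seed through a local RNG that does not disturb the
  caller's stream.

The noise model is deliberately per-spectrum rather than per-metabolite:
dilution is exactly what total-sum normalization removes, and the additive
floor decorrelates buckets. What the generator does **not** emulate: J-coupling
physics beyond fixed multiplet templates, phase/baseline errors of real raw
data, chemical-shift jitter from pH variation, inter-animal biological
variance of individual metabolites, or time-domain effects (FIDs,
apodization). Passing recovery tests therefore show the pipeline recovers
effects of the planted form at the planted noise level — they do not certify
performance on real serum data, where per-metabolite biological variation
means an unchanged mean with a fluctuating sample can legitimately cross the
|r| threshold.

# Problem sizes and numerical choices

The recovery suite runs 20 seeds of the full 3 × 8 design at 16 384 axis
points; the permutation suite runs 100 label permutations at n = 40,
p = 100; enrichment enumeration checks cover every hypergeometric
parameterization with universe ≤ 20. Exact floating-point threshold
comparisons, left-closed buckets, whole-bucket exclusion, natural-log
−log(p), and name-sorted tie-breaks are all stated above; the doublet
detector uses the two highest local maxima, so a neighbouring resonance that
outgrows lactate's lines inside the ±0.1 ppm window would miscalibrate — the
generator keeps lactate dominant there, as serum spectra do.

# Known limitations

Printed R²X/R²Y/Q² and enrichment p-values of the case study depend on its
unreleased spectra and the annotation tool's unprinted universe, and are not
reproduction targets. The bundled pharmacology pathway list is a synthetic
stand-in constructed to the published overlap structure. Pathway-name
matching across arms is by canonicalized free text, which cannot repair
arbitrary renamings — only the spelling variants the rules cover.
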