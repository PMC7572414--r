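---
title: "Multi-proxy trophic analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-proxy trophic analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multitroph)
```

`multitroph` implements the statistical core of a multi-proxy trophic-ecology
workflow for small pelagic fish (anchovy, *Engraulis encrasicolus*, and
sardine, *Sardina pilchardus*): gut-content metrics observed under the
microscope, diet DNA metabarcoding, and stable-isotope niche geometry, tied
together by a latitudinal north-vs-south comparison. This vignette explains
the models behind each stage, the tunable parameters that matter, and the
design decisions taken where the methodology left genuine latitude.

## Gut-content metrics

**Ontogenetic stage.** Anchovy below 11 cm and sardine below 13 cm total
length are juveniles. The comparison is strict: a fish at exactly the cut-off
is an adult. This matters only for boundary lengths, but the choice is
deliberate and tested.

**Stomach filling degree (SFD).** Feeding intensity is summarized as total
prey wet weight in the stomach (mg) divided by fish total length (mm), which
removes the trivial scaling of stomach capacity with body size. Prey weights
come from a per-individual biomass lookup resolved through a taxonomic
fallback chain — species, then genus, family, and prey group — with every
fallback recorded in a provenance table. Unit biomasses are user inputs, not
package constants: published length-weight conversions vary by region and
should be supplied per study.

**Composition summaries.** `%N` (numerical), `%B` (biomass) and `%FO`
(occurrence) are computed per sampling site first and then averaged,
unweighted, across the sites of a stratum, so a heavily sampled site does not
dominate the stratum mean; a pooled variant is available via
`site_average = FALSE`. For `%B`, the stratum group biomass is additionally
divided by the number of fish of the stratum before percentages are formed.
Within a site this normalization cancels in the percentage, but it is applied
as stated so that the intermediate biomass tables are themselves
sample-size-corrected. Taxa flagged as parasites are rejected outright:
parasites are excluded at the bench, so their presence in an input table
signals an upstream error.

## OTU-table hygiene

The metabarcoding filters run in a fixed, logged order; order matters because
global read fractions are computed before any per-sample zeroing:

1. OTUs below 0.005 % of all reads in the dataset are removed (sequencing
   noise);
2. cells below 0.01 % of their sample's reads are zeroed (mistagging —
   reads mis-assigned across multiplexed libraries);
3. OTUs without usable taxonomy are dropped (for the zooplankton COI marker),
   or non-diatom OTUs are dropped (for the rbcL marker);
4. OTUs of the predator genus are zeroed in samples of that host species,
   mirroring the use of blocking primers;
5. COI samples left with fewer than 20 reads are removed.

All threshold comparisons are strict — "below X" removes, a tie is retained —
because the rule is phrased as a lower bound and because strictness gives an
exact, testable contract (the test suite pins cells at exactly 0.005 % and
0.01 %). The filter log records OTUs, samples and reads removed per step; the
cascade is idempotent and total reads are non-increasing across it.

For diatom occurrence tables, two merge rules are exposed: taxa without
species-level taxonomy are pooled as "Diatom remains", and taxa whose overall
occurrence falls below a configurable percentile (default the 70th, computed
with linear interpolation over the nonzero occurrence frequencies) are pooled
as "Other diatom groups". The percentile is recomputed from the data at hand
rather than hard-coding any particular cut-off value, since the cut-off is a
property of each dataset.

## Diversity and rarefaction

Richness is a count of occurring taxa; diversity is the Shannon-Wiener index
in natural-log units. The log base is a genuine choice — the index is often
reported in bits — and natural log was chosen as the ecological convention
that matches typical reported magnitudes (1.2–1.8 for diets of 40–60 taxa).
Diatoms are excluded from richness/diversity comparisons between methods,
since the microscope cannot see them.

Between-species diet similarity uses Whittaker beta-diversity on
presence/absence,
$$\beta_w = \frac{a+b+c}{(2a+b+c)/2} - 1,$$
with $a$ shared taxa and $b, c$ exclusive taxa: 0 means identical prey
lists, 1 disjoint ones.

`rarefy_extrapolate()` interpolates expected richness with the analytic
hypergeometric expectation and extrapolates beyond the reference sample with
the Chao lower-bound estimate of undetected richness (Chao1 from
singletons/doubletons in abundance mode; Chao2 from uniques/duplicates in
incidence mode), using the bias-corrected form when doubletons are absent.
Microscope counts use abundance mode; metabarcoding presence/absence uses
incidence mode, matching what each source measures. Extrapolation is capped
at twice the reference size by default — beyond that the Chao extrapolation
is known to be unreliable — and confidence bands come from a 200-replicate
bootstrap over an estimated community that reserves the unobserved
probability mass for undetected taxa. The bootstrap count trades precision
for desk-scale runtime and is configurable.

## Niche overlap and the RA2 null

Pianka's index is the cosine similarity of two resource-utilization vectors,
$$O_{jk} = \frac{\sum_i p_{ij} p_{ik}}{\sqrt{\sum_i p_{ij}^2 \sum_i p_{ik}^2}},$$
so it is symmetric and scale-invariant; raw `%FO` or `%N` vectors can be
supplied directly. Utilization defaults to presence proportions (normalized
`%FO`), with `%N`-based vectors as an option — occurrence-based proportions
are the natural reading of "presence" in diet work, but both conventions
exist in the literature, so both are provided.

Significance uses the RA2 randomization null: each iteration replaces every
nonzero entry of *both* vectors with independent Uniform(0,1) draws and keeps
zeros fixed — zero states retained (prey absent from a diet stay absent,
reflecting patchy prey availability), niche breadth relaxed. The p-value is
the add-one estimator $(1 + \#\{O_{null} \ge O_{obs}\})/(1+\text{iterations})$,
which can never be exactly zero. The upper tail is the default because the
ecological question is "more overlap than chance"; a two-sided variant is a
flag. Groups empty in both diets are dropped first: retained zeros in both
vectors contribute nothing to the index, and dropping them makes the null
distribution independent of padding. Randomizing both vectors (rather than
holding one fixed) is the default; the asymmetric variant is exposed.
Calibration is verified in the test suite: when the observed vectors are
themselves drawn from the null, the p-values are uniform.

## Isotopic niche geometry

δ13C values from tissue with C:N strictly above 3.5 are lipid-normalized
with the aquatic correction δ13C′ = δ13C − 3.32 + 0.99 · C:N. The constants
come from the standard aquatic normalization this rule is based on and are
documented rather than buried: analyses that use a different normalization
can pre-correct and skip this step.

The isotopic niche is the standard ellipse of the (δ13C, δ15N) cloud — the
contour at Mahalanobis radius 1 of the maximum-likelihood bivariate normal.
Its area SEA = π√det Σ contains 1 − e^(−1/2) ≈ 39.3 % of the data under
normality (the familiar "about 40 %" description); the small-sample
correction is SEA~C~ = SEA · (n−1)/(n−2). The Bayesian counterpart SEA~B~
uses a conjugate Normal–Inverse-Wishart posterior with a vague prior
(Inverse-Wishart with 3 degrees of freedom — dimension + 1, the smallest
proper choice — and scale 10⁻³ I; mean precision 10⁻³), 10,000 posterior
draws by default, each covariance draw mapped to its ellipse area. With a
prior this flat the posterior is dominated by the data already at n ≈ 10;
the test suite checks that 95 % credible intervals cover the ML estimate at
nominal rate and that the posterior mean converges to it.

Directional overlap between two ellipses (the percent of A's area shared
with B, and vice versa) is computed by deterministic grid integration
(500 × 500 over the joint bounding box) with a Monte-Carlo cross-check;
full containment is detected analytically via the boundary (an ellipse is
convex, so it lies inside another exactly when its boundary does), making
the contained case exact. Overlap uses SEA~C~-scaled ellipses by default —
the small-sample-consistent choice — with the uncorrected scale behind a
flag. Ellipse fitting requires n ≥ 3 per stratum; smaller strata are dropped
and flagged, since the correction factor is undefined at n ≤ 2.

## Additive models

The regression protocol mirrors standard practice for trophic covariate
analysis: predictors are screened first (pairwise Pearson correlation below
0.70 and generalized variance-inflation factors below 3; GVIF is computed
from determinant ratios of the dummy-coded design correlation matrix so that
factors are handled correctly), the response family is chosen by an explicit
decision path (Shapiro–Wilk on the raw response; if non-normal, on the
log-transformed response; Gamma with log link when normality never holds),
and each smooth is a thin plate regression spline with basis dimension
restricted to k = 4 to avoid over-fitting at field-study sample sizes.
Smoothing parameters are chosen by GCV, with REML behind a flag. The
"gaussian-log" family is a Gaussian model of the log response — a
transformation, not a log-link GLM — matching the decision path that
produced it.

Term selection is forward-then-backward stepwise on AIC with a minimum
improvement of 2 per move (the conventional information-criterion margin),
tie-breaking toward fewer terms; the full trace is returned. One caveat
documented deliberately: GCV occasionally undersmooths an individual draw,
so a linear truth yields edf ≈ 1 in the median but single fits can wander
higher; the tests assert the median behaviour. Approximate F statistics for
smooths are reported as such — the reference distribution is approximate and
flagged accordingly.

## The synthetic-study generator

Real per-fish tables from surveys of this kind are rarely published, so the
package carries a generator whose defaults *are* the study conditions the
analysis is designed around, chosen once and fixed:

* three areas ordered north to south (GSA07 at ~42.5° N, GSA06-North at
  ~40.0° N, GSA06-South at ~37.8° N), three sites each, two species,
  30 fish per species-area stratum;
* juvenile/adult lengths drawn uniform within stratum-specific ranges, with
  the northernmost stratum holding juveniles only — mirroring the
  size-structure asymmetry such surveys report;
* per-fish diets as Dirichlet-multinomial draws over 11 prey groups
  (copepod groups, euphausiids, decapods, other malacostracans, crustacean
  remains, molluscs, cladocerans, fish eggs/larvae, others), producing the
  individual-level diet variability real stomachs show. Concentrations are
  set so that copepods dominate numerically everywhere, the krill groups are
  enriched five-fold in the south (and depleted in the north) so krill
  dominates southern biomass, northern biomass is carried by fish
  eggs/larvae, and the two species diverge in the north while converging in
  the south;
* per-fish total counts log-normal (medians 30 for juveniles, 60 for
  adults — free parameters, as no per-stratum count distributions are
  published — with an 8 % empty-stomach rate);
* a COI OTU table built from true diet presence with Poisson read depths
  (~2000 reads per present taxon), predator reads in every sample, injected
  rare OTUs kept below the global 0.005 % threshold, and 1-read mistag cells
  injected only into samples whose depth keeps them strictly below the
  0.01 % per-sample threshold — so the mistagging filter can, by
  construction, remove them all, and sensitivity is measured against ground
  truth labels;
* an rbcL diatom table with occurrence probabilities spread from 0.05 to
  0.8 (so the percentile merge has both common and rare groups) and a few
  taxa without species-level names;
* isotope values bivariate-normal per species and area with δ15N depressed
  by ~1.3 ‰ in the northernmost area, a small positive length effect on both
  isotopes, and C:N drawn over 3.1–4.3 so the lipid correction is exercised.

One seed governs everything through independent child streams, so adding a
generation stage never perturbs earlier draws and identical configurations
reproduce byte-identical tables.

**What the generator does not emulate.** Sequencing reads, chimeras, PCR and
primer bias, digestion-stage detectability, spatial autocorrelation beyond
the site means, and prey seasonality are all outside its scope. Passing
tests therefore demonstrate that the *statistical machinery* recovers known
gradients from idealized tables — not that any particular field dataset
would show them.

## The pipeline and the latitudinal summary

`run_pipeline()` chains every stage on one study and ends with a qualitative
matrix comparing the northernmost and southernmost areas per metric and
species. The percent difference uses the symmetric denominator
100·|v~N~ − v~S~| / mean(v~N~, v~S~); differences strictly below 30 % are
reported as "NLD" (no latitudinal difference), otherwise the verdict names
the larger side. The symmetric denominator was chosen because neither area
is a natural baseline; the relative-to-north variant is a flag. Latitudinal
comparisons use the site-averaged stratum metrics throughout, for
consistency with the composition summaries. Microscope-based and DNA-based
overlap triangles are computed and reported separately, never mixed, because
the two sources measure different things (counts vs. detections).

Problem sizes used by the shipped analyses — 30 fish per stratum, 1000 RA2
iterations, 10,000 SEA~B~ draws, 200 bootstrap replicates — are the
package's defaults and complete in well under a minute on a laptop; all are
configurable upward for production analyses.

## Known limitations

* Quantities are as good as the biomass lookup: missing species-level
  weights silently (but loggedly) fall back to coarser taxa.
* Metabarcoding stages are presence/absence only; no attempt is made to
  interpret read counts quantitatively.
* The SEA_B prior is vague but proper; for n < 5 the posterior is noticeably
  prior-influenced and SEA_B should be read with care.
* The approximate F tests for smooths have no exact reference distribution.
* RA1, RA3 and RA4 randomization variants are not implemented; RA2 is the
  ecologically motivated default here.
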