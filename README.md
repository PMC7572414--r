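# multitroph

Multi-proxy trophic ecology of small pelagic fish in R.

Anchovy (*Engraulis encrasicolus*) and sardine (*Sardina pilchardus*) are the
backbone of many pelagic food webs, and their diets are studied with three
complementary proxies: prey items counted under the microscope (a snapshot of
ingestion), diet DNA metabarcoding (high taxonomic resolution,
presence/absence only), and stable isotopes (assimilated diet over weeks to
months). `multitroph` implements the statistics that tie these proxies
together into one latitudinal comparison, for trophic ecologists who have the
downstream tables (fish metadata, gut counts, OTU read tables, isotope
values) and want a tested, reproducible analysis:

* **Gut-content metrics** — ontogenetic stage classification, stomach
  filling degree SFD = total prey weight (mg) / fish length (mm), biomass
  conversion with a taxonomic fallback chain, and %N / %B / %FO composition
  summaries averaged across sampling sites.
* **Metabarcoding table hygiene** — the post-clustering filter cascade
  (global 0.005 % frequency, per-sample 0.01 % mistagging correction,
  taxonomy cleanup, predator-OTU removal, < 20-read sample drop), fully
  logged, plus occurrence summaries with percentile-based diatom merging.
* **Diversity** — richness, Shannon–Wiener H′ (natural log), Whittaker
  beta-diversity β_w = (a+b+c)/((2a+b+c)/2) − 1 on presence/absence, and
  sample-size-based rarefaction/extrapolation (hypergeometric interpolation,
  Chao extrapolation, bootstrap confidence bands).
* **Niche overlap** — Pianka's index
  O = Σ p_ij p_ik / √(Σ p_ij² · Σ p_ik²) with the RA2 randomization null
  (zero states retained, niche breadth relaxed, 1000 iterations) and an
  add-one p-value.
* **Isotopic niche** — C:N-triggered lipid normalization of δ13C, standard
  ellipse areas SEA = π√det Σ (the ellipse containing ≈ 40 % of the data),
  the (n−1)/(n−2) small-sample correction, Bayesian SEA_B posteriors
  (Normal–Inverse-Wishart, 10,000 draws), and directional ellipse overlap.
* **Additive models** — collinearity screening (Pearson r < 0.70,
  GVIF < 3), a normality-driven family decision (Gaussian / log-Gaussian /
  Gamma-log), thin plate regression splines with k = 4, GCV smoothing, and
  forward-backward AIC stepwise selection.
* **A synthetic-study generator** — Dirichlet-multinomial gut counts with a
  configurable north-to-south shift from copepod-dominated to krill-enriched
  diets, OTU tables with ground-truth rare-OTU and mistagging noise, and
  bivariate-normal isotopes with a northern δ15N depression, so the entire
  workflow is testable end to end without unpublished field data.

## A worked example

Generate a synthetic study with the default latitudinal gradient and run the
full analysis:

```r
library(multitroph)
p <- run_pipeline(seed = 1)
p$latitudinal
```

```
                metric species value_north value_south percent_difference verdict
                   SFD anchovy        0.11        1.17             165.72   S > N
           %N copepods anchovy       79.82       66.09              18.82     NLD
              %N krill anchovy        0.21       23.01             196.42   S > N
              %B krill anchovy        1.69       96.56             193.10   S > N
 richness (microscope) anchovy       14.00       21.00              40.00   S > N
            Shannon H' anchovy        1.73        2.08              18.22     NLD
              delta15N anchovy        8.07        9.60              17.33     NLD
              %B krill sardine        5.89       96.23             176.95   S > N
              delta15N sardine        8.40        9.75              14.86     NLD
                   ...
```

Each row compares the northernmost area (GSA07) with the southernmost
(GSA06-South): the percent difference uses the symmetric denominator
100·|vN − vS| / mean(vN, vS), and differences below 30 % are reported as
"NLD" (no latitudinal difference). Here the configured southern krill
enrichment is recovered as "S > N" for krill %N and %B in both species —
krill carries 96 % of the southern biomass versus 2–6 % in the north — and
mean δ15N is about 1.4 ‰ lower in the north (8.07 vs 9.60 ‰ for anchovy), as
configured, though below the 30 % verdict threshold.

Individual stages are ordinary functions on plain tables:

```r
study <- generate_study(study_config(seed = 1))
filtered <- filter_otu_table(study$otu_coi)
filtered$log                      # what each filter removed
pianka(c(0.5, 0.5, 0), c(0.5, 0, 0.5))   # 0.5
ra2_null_test(c(.7, .2, .1, 0), c(.1, .1, .8, 0), iterations = 1000, seed = 1)
fit_standard_ellipse(cbind(rnorm(40, -19), rnorm(40, 9)))
```

The methods vignette (`vignettes/multiproxy-methods.Rmd`) documents every
model, default and design decision.

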