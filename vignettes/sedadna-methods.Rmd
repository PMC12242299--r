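---
title: "Inference from replicated sedimentary ancient DNA metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference from replicated sedimentary ancient DNA metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedadna)
library(dplyr)
```

## The inference chain

Sedimentary ancient DNA (sedaDNA) metabarcoding reads a biodiversity
archive out of dated marine sediment: each sampled depth horizon is
extracted, PCR-amplified in several independent replicates with a short
taxonomically informative marker (such as the ~130 bp eukaryotic 18S V9
fragment), sequenced, and denoised into amplicon sequence variants (ASVs).
`sedadna` implements everything downstream of the ASV tables:

1. **Curation** of the per-lane, per-orientation count tables: orientation
   merging, post-clustering error-daughter merging, singleton and
   replicate-support filtering, negative-control thresholding, amplicon
   length filtering, and lane combination.
2. **Taxonomy** from alignment hit tables: lowest-common-ancestor (LCA)
   assignment, strict high-confidence assignment, all-hit consensus
   functional annotation, and genus-level merging of ASV counts.
3. **Detection statistics**: mean relative proportions, ASV richness, the
   proportion of positive PCR replicates per sample (the package's central
   semi-quantitative abundance proxy), and its regression against
   interpolated climate covariates.
4. **Chronology**: a Monte-Carlo piecewise-linear age-depth model over
   calibrated dated horizons.
5. **Zooarchaeological context**: weighted centennial marine-versus-
   terrestrial proportions from NISP assemblage tables.
6. A **synthetic experiment generator** with known truth, so that every
   stage is testable without any sequencing data.

All user-facing functions take plain tibbles and return tibbles, so the
stages chain with the pipe; fitted objects (`age_model`,
`detection_ols`) carry `tidy()`, `glance()` and `autoplot()` methods.

## The detection-proportion statistic

For a taxon in a sample with $R$ independently processed PCR replicates,
the detection proportion is

$$\hat p = \frac{\#\{\text{replicates with } > 0 \text{ reads after curation}\}}{R}.$$

Replicate positivity is `count > 0` after curation, with no extra minimum
read threshold: the curation cascade is the error model, and adding a
second ad hoc threshold would double-count it. Counts of all ASVs assigned
to the same genus are merged within each replicate first, so $\hat p$
tracks the genus rather than any single sequence variant. Replicates
absent from the curated table are excluded from numerator and denominator
alike. Under an occupancy-style view, $\hat p$ estimates the per-replicate
detection probability $p$, which the simulator links to an SST-like
covariate $x$ through $\mathrm{logit}(p) = \beta_0 + \beta_1 x$.

## Curation: parameters and conventions

The cascade runs per sequencing lane, in a fixed order, then combines
lanes. The order matters and is pinned by a regression test: the singleton
rule runs *before* negative-control thresholding, so a stray single read
in a blank does not inflate the contamination threshold.

* **Orientation merge.** Libraries built with the amplicon in both
  orientations are demultiplexed twice; the reverse table is
  reverse-complemented and counts are summed for exactly identical
  sequences. Reads are conserved exactly.
* **Error-daughter curation** (`lulu_curation()`). A daughter merges into
  a parent when the parent is more abundant in total, global-alignment
  identity is at least 99%, the parent co-occurs in at least 95% of the
  daughter's replicates, and the minimum parent/daughter ratio over
  co-occurring replicates is at least 1. The 99% identity is the
  published setting for this curation style; ratio and co-occurrence are
  the cited tool's defaults. Alignment is Needleman–Wunsch with match +1,
  mismatch −1, gap −2, and identity is matching columns over all
  alignment columns — a deliberately simple, deterministic scoring.
  Qualification is decided on the input table; daughters are processed in
  ascending abundance and counts flow along merge chains to the ultimate
  surviving parent, so reads are conserved. When several parents qualify,
  the highest identity wins, with ties broken by abundance then
  lexicographic id.
* **Singleton / replicate support.** Cells with exactly one read are
  zeroed ("singleton observations" read as per-cell counts, since the
  protocol pairs them with per-replicate support; a dataset-total reading
  would be a different filter), then ASVs supported by fewer than two
  replicates in the lane are dropped.
* **Negative-control threshold.** For each ASV, $\tau$ is the arithmetic
  mean of its counts over *all* negative controls of the lane
  (extraction, PCR and library blanks; zeros included). Sediment
  observations with `count <= tau` are zeroed. The source protocol prints
  the rule in the opposite direction ("more than the average … set to
  zero"); taken literally that deletes the strongest biological signal
  and keeps the contamination-level noise, so the corrected reading is
  the default and the literal one is available as `literal = TRUE` for
  exact replication. $\tau$ per ASV and lane is recorded in the curation
  report.
* **Length filter.** ASVs outside 70–170 bp (inclusive bounds, the
  plausible V9 amplicon range) are removed.
* **Lane combination.** Identical sequences are summed across lanes
  within replicates; reads conserved.

Every stage's ASVs and reads in/out are audited in a `CurationReport`
tibble; totals can only decrease, and the three merge stages conserve
reads exactly.

## Taxonomy conventions

Lineages use a fixed seven-rank convention
(domain;phylum;class;order;family;genus;species); shorter lineages are
right-padded as unassigned, and an unassigned rank terminates the common
prefix — it never matches anything, including itself, which prevents
spuriously deep agreement between incomplete references.

`lca_assign()` keeps hits at or above the identity/coverage thresholds,
retains at most 200 best-bitscore hits (all hits tied at the cutoff are
kept, so the result is independent of input order), and assigns the
longest lineage prefix common to every retained hit. No bitscore-margin
filter is applied by default, since the underlying protocol specifies
none. `high_confidence_assign()` is the same computation with strict
inequalities — identity > 99% and coverage > 90% (general) or > 95%
(vertebrate preset); a hit at exactly 99.0% is excluded.
`consensus_annotation()` transfers a categorical label only when every
hit above 85% identity and 90% coverage carries the identical label; it
is equivalent to LCA on a one-level taxonomy, and a property test pins
that equivalence. Query coverage is aligned query length over query
length, end gaps excluded.

## Chronology

`build_age_model()` is a deliberate simplification of fully Bayesian
accumulation-rate age models: each draw samples every horizon's age from
$\mathcal N(\mu_i, \sigma_i)$, draws that violate monotone deposition are
rejected (the direction of time with depth is taken from the dated means
themselves, so both calendar-year and age-BP conventions work), and ages
between horizons are piecewise-linear with linear extrapolation at the
ends. No prior is placed on sedimentation rate — the package's downstream
statistics consume only the per-depth posterior mean, for which the
linear Monte-Carlo model converges to the deterministic interpolation
(tested to within three standard errors at 2000 draws). Rejection
sampling is capped at 100× the requested draws, and failure names the
horizon pair that most often reversed. Calibration and reservoir
correction (e.g. ΔR = 200 ± 50 for the regional marine reservoir) are
assumed already applied to the input ages; the model does not attempt
them. Samples are dated at the midpoint of their sampled span, and depths
more than 10% of the model span outside the dated range trigger an
extrapolation warning. Calendar time is astronomical years CE (1315 BCE
is −1314), which keeps regressions free of year-zero arithmetic.

## Regression and smoothing

`ols_detection_vs_covariate()` interpolates the proxy linearly to each
sample's mean age (samples outside the proxy span are dropped, with a
count reported), then fits ordinary least squares. With a grouping term
(sediment core) the model can carry separate intercepts and,
optionally, separate slopes; the slope-equality test is the F test of
the interaction terms. Both the intercept-offset and full-interaction
parameterisations are supported because a three-numerator-df fit over two
cores admits either reading; neither is asserted as canonical. The
detection proportion is bounded, so OLS is a linear-probability-style
approximation; the simulator's acceptance suite verifies that under the
logit truth the fitted slope is sign-correct and unbiased against the
induced linear-approximation slope.

`lowpass_smooth()` provides the 100-year first-order low-pass trend used
for proxy visualisation: a local linear fit with tricube weights over a
fixed window, one-sided at the ends. It recovers constants exactly and
linear trends to numerical precision in the interior, and attenuates a
20-year oscillation under a 100-year window to below 20% amplitude. It is
*not* equivalent to penalized-regression splines fitted by REML, which
the source analysis used for its trend figures; the package deliberately
omits that machinery because the curves are visual aids with no role in
the reported statistics.

## Zooarchaeological weighting

Each assemblage's weight is one over the number of centuries its dating
spans (a two-century assemblage contributes 0.5 in each), so its total
influence over time is one collection regardless of dating precision. The
centennial marine proportion is the weighted mean of per-assemblage
marine NISP shares across assemblages covering the century; computing
shares per assemblage before weighting follows the wording of the
weighting scheme, and pooled weighted-NISP summation is available behind
`pooled = TRUE`. Century $n$ covers years $(n-1)\cdot 100 + 1$ to
$n\cdot 100$ CE, matching "ninth century" for the settlement era. A
`region` column supports the sensitivity view restricted to sites near
the sediment records.

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the emulated study design: two cores of
158 and 46 samples, eight PCR replicates per sample distributed over
three sequencing lanes, negative-binomial replicate totals with mean
170 000 reads (dispersion 4, giving a standard deviation near 85 000),
extraction/PCR/library blanks on every lane, Poisson contaminant reads in
blanks with mean 150 (the observed order of magnitude), contaminants at a
tenth of that rate in sediment replicates (template competition
suppresses contaminant amplification where real template is abundant),
low-rate leakage of the most abundant real ASVs into blanks (so the
threshold filter faces hard cases, not only easy ones), 1-mismatch error
daughters at sub-5% of parent abundance, and within-lane tag jumps at
rate 0.001 — the library design minimises tag jumps, so the default is
small but non-zero. Detection follows a logit link,
$\mathrm{logit}(p) = \beta_0 + \beta_{\text{core}} + \beta_1 z(x)$, with
core-specific intercepts and a shared slope, mirroring the slope-equality
design; the default herring-like taxon has $\beta_1 = 1.5$. Reads are
allocated over occupied taxa by a Dirichlet-multinomial, hit tables are
generated from the true lineages with identity jitter (same-species hits
above 99%, congeners at 95–99%, family-level relatives below), and every
draw is reproducible from the config seed.

The generator works at the count level. It does not simulate reads,
quality scores, chimeras, PCR cycle effects, or post-mortem DNA damage,
and its taxa are exchangeable caricatures rather than a community model.
Passing tests on simulated data therefore validate the *inference
machinery* — filter logic, threshold arithmetic, estimator bias — not the
biological fidelity of any real dataset.

A `detection_only` fast path skips read-level simulation and returns the
occupancy-level truth; the repeated-seed slope-recovery study uses it
because the read layer is irrelevant to the detection-proportion
regression, while a full read-level run at the same design exercises
contamination removal and daughter merging.

## Numerical choices and problem sizes

Integer counts round-trip bit-exactly through the TSV writers; reals are
written at 12+ significant digits. Merge representatives are the most
abundant contributing ASV id, ties broken lexicographically. The test
suite sizes its simulations to the smallest scale that still exercises
every code path (tens of samples, thousands of reads per replicate); the
slope-recovery study runs 200 seeded occupancy-level experiments at 150
samples × 8 replicates with a ~10⁵-draw Monte-Carlo oracle, and one full
read-level experiment at the same design for artefact recovery. These
sizes are the package's own reproducibility choices and complete in
about a minute and a half.

## Known limitations

* The age model ignores accumulation-rate priors; posterior intervals are
  narrower than a Bacon-style model would give, and only the means should
  be consumed.
* OLS on a bounded proportion can predict outside [0, 1]; for inference
  on detection probabilities near the boundary an occupancy model would
  be preferable (deliberately out of scope).
* The LCA implementation weights all retained hits equally; no
  taxon-frequency or bitscore weighting is applied.
* The negative-control rule assumes blanks share the lane's contamination
  profile; it cannot remove sample-specific (e.g. cross-well)
  contamination, which only the replicate-support filter addresses.
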