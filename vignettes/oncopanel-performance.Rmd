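---
title: "Measuring oncopanel analytical performance: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring oncopanel analytical performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(panelmetrics)
```

Targeted cancer sequencing panels (oncopanels) are validated against
characterized reference samples: an admixture sample carrying tens of
thousands of known positive variants (KPs) across a wide range of variant
allele fractions (VAFs), a diploid normal, a 1:1 mixture of the two, and a
spike-in sample with synthetic hotspot variants at a fixed 5% VAF. Each
sample is sequenced in replicate libraries at several laboratories, vendors
call variants, and the call sets are scored against the known content. This
package implements the scoring side of that design: VAF-stratified
sensitivity, three complementary false-positive (FP) rate estimators, a
non-symmetric reproducibility measure, the genomic sub-region partition the
metrics are stratified over, and a two-component model of the coefficient of
variation (CV) of tumor mutational burden (TMB) estimates. A synthetic study
generator reproduces the statistical structure of the design so every
estimator can be validated against known generative parameters.

## Regions and coordinate conventions

Truth content is only defined in curated regions: the consensus targeted
region (CTR), a high-confidence coding subset where the KP and
known-negative (KN) catalogs live, contained in the broader high-confidence
coding region (HC_CR). Intersecting these with a panel's target yields three
disjoint evaluation sub-regions (`build_subregions()`): inside the CTR,
inside the HC_CR but outside the CTR, and the rest. Their union is exactly
the panel target; this conservation is enforced by tests against a per-base
mask oracle.

Conventions, applied uniformly:

* BED input/output is 0-based half-open; internally regions are `GRanges`
  and the conversion happens exactly once, at the file boundary.
* Normalization sorts and merges overlapping *and bookended* intervals, so
  sizes in bases are unambiguous.
* Chromosome names are compared as exact strings. No "chr" aliasing is
  attempted; silent aliasing hides input errors.
* A variant's region membership is decided by its anchor base (leftmost
  reference position). This is a single unambiguous rule; users who need
  overlap-aware membership for long indels can pad their regions.

## Call normalization and matching

Vendor VCFs differ in representation, so calls are normalized before any
matching: multiallelic records are split per alternate allele, alleles are
trimmed to parsimony (shared suffix first, then shared prefix, advancing the
position), and variant type is assigned (SNV, MNV, INDEL by allele
lengths). Matching — against truth catalogs and between libraries — is then
exact on the `(chrom, pos, ref, alt)` key. Distance-window or
haplotype-aware matching would silently change every downstream metric, so
it is deliberately not offered. Full left-alignment through repeat tracts
requires the reference sequence and is not performed; call sets must be
normalized to a shared convention, which holds for the package's own
generator and for pipelines that pre-normalize with standard tools.

The per-record VAF is taken from a configurable source priority
(`INFO/AF`, then `FORMAT/AF`, then derived from `FORMAT/AD`), because
vendors do not report a uniform field.

## Sensitivity

Sensitivity is the portion of known positives detected, pooled over
libraries: total detections divided by (targeted KPs x libraries). An
averaged per-library variant is available (`method = "average"`); pooling is
the default. Stratification uses the *expected* (characterized) VAF of the
truth catalog, never the observed VAF — the boundary-effect analysis is
meaningless otherwise. Strata are half-open `(low, high]` with the lowest
stratum closed below, so the standard ranges 1–2.5%, 2.5–5%, 5–10% and
10–20% partition the axis without double counting. Expected VAFs follow the
mixture arithmetic: sample C, a 1:1 dilution of the admixture sample with
the diploid normal, carries half the sample-A VAF, and KPs coinciding with
a normal-sample germline variant are excluded from C truth (their VAF is
the sum of both contributions). Spike-in truth sits at 5% by construction.

Confidence intervals use a two-stage clustered bootstrap: laboratories are
resampled with replacement, then libraries within each sampled lab, and the
percentile interval of the pooled statistic is reported (default 1000
resamples). Library replicates within a lab are not independent; resampling
labs first is the standard conservative scheme for that dependence. With a
single lab and a single library the interval degenerates to the point
estimate and is flagged.

`cutoff_sweep()` removes calls below an artificial VAF cutoff before
matching. Because a variant's sampled VAF straddles a nearby threshold
across replicates (alt reads are binomial), sensitivity for a stratum just
above the cutoff degrades as the cutoff rises — the boundary effect. The
package's generator reproduces the mechanism exactly, and the closed-form
binomial tail (`detection_probability()`) is the oracle the estimates are
tested against.

## False-positive rates

Three estimators with different blind spots:

* **viaKN** — calls landing on known-negative positions. Defined only
  inside the CTR (the KN list exists only there); the rate is FP calls per
  million KN positions. Multiple alternate alleles at one KN position count
  as distinct FP calls.
* **B_low** — calls in the diploid normal with VAF in the 1–10% window
  (boundaries inclusive). True variants in a diploid normal sit near 50% or
  100%; low-VAF calls there are errors, except calls whose variant appears
  above 10% VAF in a sibling replicate at the same lab (excluded; such
  support suggests a real mosaic signal rather than noise). May
  overestimate by counting rare cell-line mosaics.
* **C_only** — mixture exclusivity: a sample-C call absent from all of the
  lab's sample-A libraries (at any VAF) and from its sample-B libraries
  above 10% VAF. Blind to systematic errors, which recur in all samples.

B_low and C_only use the evaluated region size in bases as denominator
(rates per Mb) and apply outside the CTR too, which is what exposes the
region gradient: with the generator's four-fold higher error rate outside
the CTR, the estimated sub-region rates recover the injected ratio.
`fp_reproducibility()` reports the fraction of distinct FP variants
recurring in two or more libraries; independent errors essentially never
recur, so recurrent FPs are systematic-error candidates and are listed, not
adjudicated.

## Reproducibility

For an ordered pair of libraries of the same sample, reproducibility is the
portion of the first library's calls (optionally restricted to a VAF
stratum applied to the first library only) that the second library also
calls, matched by key with no restriction on the second library's VAF. The
measure is directional: with four calls in one library and two of them in
another, the two directions give 0.5 and 1.0. Aggregation averages over all
ordered pairs, split into intra-lab (pair shares a lab) and cross-lab
scopes. Values are displayed on the Phred scale as `-10 log10(1 - r)` — the
standard error-probability mapping of the miss fraction `1 - r` — with a
perfect value capped at 60 (configurable), since the transform diverges at
1.

## TMB coefficient of variation

Reference samples are far denser in low-VAF variants than tumors, which
would distort a naive run-to-run TMB variability estimate in two opposite
ways: the density (equivalent TMB near 1000) drowns the FP contribution,
and the low-VAF excess inflates detection noise. The thinning simulation
(`technical_cv()`) therefore rebuilds tumor-like samples from sample C
inside the CTR: germline variants of the normal sample are removed from
both the KP list and the call sets, KPs with sample-A VAF below 5% or above
40% likewise (leaving expected sample-C VAFs between 2.5% and 20%), and for
a retention percent `k` each remaining KP is kept with probability `k`% (VAF
10–40%) or `0.5 k`% (VAF 5–10%). Positions of non-retained KPs are excluded
from the report region, so any call there — FP or uncharacterized — is
dropped. Per round, reported calls above a VAF cutoff are counted per
library; the technical CV is

```
CV = sqrt(mean over rounds of across-replicate variance) /
     mean over rounds of across-replicate mean count
```

and the simulated TMB is the mean count over the report-region size. The
default is 5000 rounds as in the full-scale design; the test suite and the
examples use 300–500 rounds, which agree with the closed-form compound
binomial + Poisson oracle within Monte-Carlo error. `k = 0` rounds contain
only the FP floor and are excluded from CV estimation.

The intrinsic component asks a different question: even with perfect
sequencing, how much does projecting an exome-level TMB onto a small panel
scatter? Given a per-sample mutation catalog with exome TMB `t_i`, the
panel projection divides each sample's mutation count inside the panel's
covered region (panel ∩ CTR ∩ CDS) by that region's size; panels under
250 kb are rejected as too small to project meaningfully. Samples with TMB
in 5–40 are sorted and cut into groups of 100, and the mean squared
deviation between reference and panel TMB is decomposed per group into a
mean-bias term and an *adjusted variance* — the variance of panel TMB minus
the variance of reference TMB within the group. Population (1/N) variances
are used so the decomposition identities hold exactly. Samples deviating
from their group's mean deviation by more than five group standard
deviations are excluded and logged (generalizing single-outlier removal to
a rule).

Converting the adjusted variance to the mutation-count scale (multiplying
by squared panel size) and regressing it through the origin on the mean
panel count pools all groups of all panels; the slope is the count-level
index of dispersion and its square root the coefficient of
`intrinsic_cv(c) = coef / sqrt(c)`. A free-intercept fit is reported as a
diagnostic only: the CV relation itself implies proportionality through the
origin. The recovery of a known dispersion by this regression is only exact
in the small-sampling-fraction regime — for a panel covering a fraction `q`
of the shared region the slope is depressed by roughly `q` times the mean
cluster size — so the package's recovery experiments use panels covering
1.5–4% of the shared region, matching the actual ratio of oncopanel CTR
footprints to the exome-wide shared region. The reference coefficient 1.15
from large-scale catalog analysis is shipped as the named constant
`reference_intrinsic_coef` for replication; fitted analyses always use the
coefficient estimated from the supplied catalog.

Technical and intrinsic CVs arise from independent mechanisms (measurement
noise vs genomic subsampling) and combine in quadrature:
`overall_cv()` returns `sqrt(cv_tech^2 + cv_intr^2)`. At a mean count of 21
on a 1-Mb panel the reference relation gives an intrinsic CV of
`r round(100 * intrinsic_cv(21, coef = 1.15))`%.

## The synthetic study generator

The generator's defaults are the study conditions, chosen once:

* Toy genome of three 10-Mb chromosomes; HC_CR 3.0 Mb, CTR 2.0 Mb inside
  it, panel target = CTR + 0.6 Mb of HC_CR beyond the CTR + 0.5 Mb outside
  the HC_CR.
* 4000 KPs uniform in the CTR (the same ~2 per kb density as the reference
  catalogs), VAF spectrum 7% / 18% / 25% / 18% across the four low-VAF
  strata with the remainder above 20%, and 1.2% of KPs non-SNV.
* One million KN positions — about half the CTR, mirroring the real
  catalog's coverage — disjoint from KP loci by construction.
* 1000 diploid germline variants (VAF 50% or 100%), 5% of them coinciding
  with KP loci to exercise the exclusion rules; 300 spike-in variants at
  5% VAF.
* Three labs, four replicates per sample; mean depth 1000 (sample C at
  2000), drawn per variant from a negative binomial with size 60 — a
  documented stand-in, as real per-panel depth targets are vendor-specific;
  reporting threshold 1% VAF and at least 3 alt reads.
* Error calls injected as a Poisson process at 5 per Mb per library inside
  the CTR and 20 per Mb outside, with VAFs from a shifted exponential
  (`0.01 + Exp(0.015)`): most mass below 5% and essentially none above 10%,
  in line with observed FP VAF profiles, and with a closed-form tail for
  the oracles.

Every call carries its generative origin, so parameter-recovery tests can
compare estimates against injected truth with analytic standard errors. The
generator does **not** emulate read-level errors, sequence-context or
FFPE artifacts, primer interference around dense spike-in clusters, CNV, or
vendor pipeline differences. Passing recovery tests therefore demonstrates
that the estimators are correct for the design they implement — not that
any particular real panel achieves these numbers.

## Numerical and testing choices

* All stochastic operations accept seeds; identical seeds give identical
  bundles.
* The bootstrap-coverage experiment simulates 500 studies of 6 labs x 4
  replicates x 40 KPs with lab effects of sd 0.4 on the logit scale around
  a base sensitivity of 0.88. Six labs rather than the consortium minimum
  of three: with three clusters a percentile bootstrap's resampling
  distribution is too coarse for a coverage experiment to measure anything
  but small-cluster artifacts.
* Technical-CV oracle comparisons treat the call sets as the one fixed
  realization they are (only the thinning is re-randomized, as in the
  original design), so comparison standard errors combine the across-round
  Monte-Carlo term with the study-level spread of an across-replicate
  sample variance.
* Degenerate inputs are flagged, not silently zeroed: empty strata are
  "not assessable", a reproducibility pair with no stratum calls is `NA`,
  zero FPs make recurrence undefined.

## Limitations

Exact-key matching means representation differences between call sets that
were not normalized to the same convention count as mismatches. The MNV
decomposition question (block vs decomposed matching) is resolved by
matching keys as submitted. Sensitivity outside the HC_CR cannot be
assessed at all — there is no truth there — and the generator places no
truth outside the CTR for the same reason, which is why sub-region
comparisons of sensitivity use synthetic truth confined to the CTR while FP
and reproducibility comparisons span all three sub-regions.
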