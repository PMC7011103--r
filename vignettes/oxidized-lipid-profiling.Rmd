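---
title: "Targeted profiling of oxidized membrane lipids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted profiling of oxidized membrane lipids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxlipidr)
```

## The problem

Salinity and other oxidative stresses peroxidize the polyunsaturated acyl
chains of plant membrane lipids, producing oxylipin-containing
glycerophospholipids (ox-PC, ox-PE, ox-PG, ox-PI, ox-PS) and galactolipids
(ox-MGDG, ox-DGDG). These species are low-abundance and not covered by
standard lipidomics libraries, so they are identified by a targeted strategy:
enumerate plausible oxidized species in silico, predict their negative-mode
precursor and fragment masses, and accept only those candidates supported by
accurate precursor mass, diagnostic MS/MS fragments, and a plausible
retention time. `oxlipidr` implements that strategy end to end, from
candidate generation through differential abundance statistics.

## The candidate model

An oxidized diacyl lipid is modeled as a lipid class plus two acyl chains.
A chain is the triple (carbons `n`, double bonds `d`, extra oxygens `x`),
with free-acid formula C(n)H(2n−2d)O(2+x); `x` is the count of oxygens beyond
the two carboxyl oxygens and maps to the `-O` / `-2O` label suffix. The
default chain sets are the three most abundant normal fatty acids (16:0,
18:2, 18:3) and the five 18-carbon oxylipin types (18:2-O, 18:3-O, 18:4-O,
18:2-2O, 18:3-2O). Each candidate carries either one normal FA plus one
oxylipin, or two oxylipins, so the total number of extra oxygens lies in
1–4. With the seven default classes this enumerates 30 chain compositions
per class, 210 in all. Candidates are keyed by chain composition; two
compositions can share one species label (for example PE(18:2-O/18:3) and
PE(18:3-O/18:2) both label as PE(36:5)-O) and both are kept, because real
samples contain such mixtures.

The neutral formula is constructive: glycerol (C3H8O3) + both free acids −
2 H2O + a class head-group increment (PC +C5H12NO3P, PE +C2H6NO3P,
PG +C3H7O5P, PI +C6H11O8P, PS +C3H6NO5P, MGDG +C6H10O5, DGDG +C12H20O10).
The monitored ion is class-specific: acetate adducts [M+OAc]− for PC, MGDG
and DGDG (ammonium-acetate mobile phases), deprotonated [M−H]− for PE, PG
and PI, and the serine-loss ion [M−H−C3H5NO2]− for PS. The adduct
assignment is an inference made while reconciling the curated reference
masses — the source measurements do not state it explicitly — and it
reproduces all curated detected precursors to ≤ 1.6 mDa, with a single
internally inconsistent printed row (PI(36:5)-O) discussed below.

Fragment chemistry: collision-induced dissociation releases each chain as
its carboxylate anion (free acid − H). Chains with two extra oxygens undergo
an additional in-source dehydration, so the 18:3-2O chain is detected as the
18:4-O anion (291.196) and 18:2-2O as the 18:3-O anion (293.212). No
electron-mass correction is applied anywhere: the curated fragment values
match neutral-formula-minus-H arithmetic only without the electron term, so
the package treats all anion m/z as plain formula arithmetic. Atomic masses
are fixed to C 12.000000, H 1.00782503, N 14.00307401, O 15.99491462,
P 30.97376151, with a 13C–12C spacing of 1.0033548 Da; they ship in an
overridable YAML configuration. Display rounding is half-away-from-zero at
3 decimals; matching always uses unrounded values.

## Annotation

Feature filtering follows the usual extraction settings: m/z 100–1600, RT
0.5–16 min, intensity ≥ 300 in at least 3 samples of a group, and an
isotopic-partner requirement (a co-eluting feature one 13C spacing away,
either direction, within ±0.01 Da and ±0.2 min). The replicate filter's
group scope is configurable (`"any"` group suffices by default; `"all"`
demands every group). Cross-batch alignment uses ±0.01 Da and 5 % relative
RT after an optional single-point internal-standard shift, with ambiguities
resolved by nearest m/z then nearest RT.

Matching uses 5 ppm for precursors in MS1 and 10 ppm for fragments in MS/MS,
the calibrated accuracy of the instrument class this workflow targets. A
feature–candidate pair within 5 ppm is an `MS1_ONLY` match; spectra whose
precursor matches the feature within the same tolerance and within ±0.2 min
are searched for predicted fragments, and finding at least one
oxidized-chain fragment upgrades the match to `MS1_MS2`. The normal-chain
fragment improves ranking but is not required — verification hinges on the
diagnostic oxidized fragment. Ranking is by absolute ppm error, then
fragments found, with ties broken by lower precursor m/z then label, so
output is reproducible.

Retention-time plausibility is ordinal, not predictive. Rule A: an oxidized
lipid elutes earlier than its non-oxidized parent. Rule B combines the two
reversed-phase elution statements — fewer carbons elute earlier; at equal
carbons, more double bonds elute earlier — into a partial order: within a
class and at equal extra-oxygen count, species `a` must elute no later than
`b` when `a` has no more carbons *and* no fewer double bonds (one strictly).
The two statements are deliberately not totalized into a single carbon
ordering: species differing in both directions (34:3 vs 36:5) are
chromatographically incomparable, and the curated RTs themselves contain
pairs that would violate a carbons-only rule while satisfying the product
order everywhere. Violations are flagged, never dropped; violation-free
MS/MS-verified matches reach tier `MS1_MS2_RT`.

## Quantification

Species are quantified from fragment extracted-ion chromatograms (100 ppm
window width). Each fragment's chromatogram is integrated separately and the
areas are summed — per-fragment-then-sum, chosen over summed-trace-then-peak
because it keeps each transition's baseline independent. Fragment sets per
category: all chain carboxylates for diacyl GP/GL and cardiolipin; all
FA-neutral-loss products for DAG; the long-chain base plus its first three
dehydration ions for Cer/HexCer; the single dehydrated backbone for sterols.

Integration emulates vendor settings "noise percentage 40 %, Gaussian smooth
width 2 points" with documented semantics, since the vendor algorithm is
proprietary: smoothing is a Gaussian kernel with sigma = 2 sample intervals;
the baseline threshold is 40 % of the robust background level (median of the
smoothed trace, which on baseline-dominated chromatograms estimates the
background); the area is the trapezoidal integral of the raw trace over the
contiguous above-threshold region containing the apex. The contract is:
monotone in the parameter, 0 % keeps everything above zero, and integration
is linear in intensity and invariant to time shifts. On a noiseless Gaussian
peak sampled across a baseline-dominated window the recovered area is within
2 % of the closed form A·sigma·sqrt(2*pi).

Normalization multiplies raw areas by `(reference_is / is_intensity) *
(250 / weight_mg)`, i.e. to the batch-median internal-standard response and
the equivalent of 250 mg fresh weight. The batch median is the package's
choice of reference; the source workflow used a "manual scale factor"
without a formula. Pooled-QC filtering removes lipids whose percent CV over
repeated pooled-QC injections is ≥ 25 % and reports the median CV of the
retained set.

## Statistics

Fold changes are `log2(mean(treated)/mean(control))` — means, not medians,
matching the ratio-of-responses definition. Significance is a two-sided
two-sample t test, Student (pooled variance) by default with Welch available
by flag; the source analysis does not state its variance assumption, so the
default is documented rather than inferred. Degenerate inputs follow fixed
conventions (both groups constant and equal: p = 1; constant but different:
p = 0). Benjamini–Hochberg adjustment is applied within each variety's
family of contrasts, and `bh_adjust()` delegates to `stats::p.adjust`; the
test suite compares it against an independent definitional implementation.
Class summaries sum member lipids per sample before any log transform, then
compute per-variety log2 fold changes and a lipid × (variety × treatment)
group-mean matrix, optionally row-standardized for heatmaps.

## The synthetic-data generator

No raw LC-MS data are deposited for this workflow, so the generator defines
the study conditions under which the pipeline is validated: 4 varieties × 2
treatments × 5 replicates with 5 pooled-QC injections, mirroring the
source design; planted MS1 errors Normal(0, 1.5 ppm) truncated at ±4.5 ppm
(inside the 5 ppm matching tolerance by construction); decoy features at
least 20 ppm from every candidate; isotope partners one 13C spacing up;
lognormal multiplicative abundance noise at CV 10 % (the typical pooled-QC
reproducibility of this assay class) with mean-corrected draws so fold
changes are unbiased; and a linear RT model (0.25 min per carbon, −0.55 per
double bond, −0.9 per extra oxygen) whose signs make the elution rules hold
by construction. The quantitative experiment defaults to the 38 curated
species. Weights (230–290 mg) and internal-standard intensities are jittered
and inverted into the raw areas so normalization is genuinely exercised.

What passing tests show — and do not show. The generator produces
centroided, well-calibrated, single-analyte features with known ground
truth; it has no chromatographic peak-shape physics, no co-eluting isobars
beyond label collisions, no instrument drift, and no missing values. Perfect
recall on synthetic spike-ins therefore validates the bookkeeping,
tolerances and tiering logic, not the hard parts of real data (chimeric
spectra, in-source fragmentation, matrix effects). Planted fold-change
recovery is scored per lipid as the mean of the four per-variety estimates:
the design plants the same effect in every variety, and a single n = 5 vs 5
contrast at CV 10 % has a sampling SD of ≈ 0.09 log2 units, so per-variety
estimates cannot individually sit within ±0.15 with high probability — the
per-lipid average (SD ≈ 0.046) is the quantity the design actually pins
down.

## Numerical choices and degenerate inputs

Formula subtraction that would drive an element negative raises an error
naming the element. Zero-variance t tests and zero control means return
documented conventions rather than NaN. Empty spectra lists, all-zero
traces, and zero-match annotations are valid results, not errors. All
writers emit stable row and column order; m/z is serialized at ≥ 4 decimals
and displayed at 3. Tests and the acceptance script use problem sizes that
keep the full suite under a minute: the complete 210-candidate library with
~350 synthetic features for the end-to-end check, 1,000 random vectors for
the FDR cross-check, and 1,000 simulations for the type-I error check.

## Known limitations

* The curated reference transcribes its source table verbatim, including a
  few internally inconsistent printed values (flagged in its `note` column):
  one precursor (PI(36:5)-O, printed 871.487 where the constructive formula
  and the neighboring homologs give 871.497), three fragment entries, and
  the 18:3 carboxylate printed as 277.216 where it computes to 277.217.
  Computed values are canonical everywhere in the package.
* One curated species, PS(34:4)-2O, implies a 16:1 or 18:4-2O chain that
  lies outside the stated default chain sets; the default enumeration
  therefore covers 37 of the 38 curated species. The sets were not widened,
  because they are the workflow's stated chemistry; the species remains
  reachable by passing custom chains to `ox_candidate()`.
* Lyso (monoacyl) oxidized species, triacyl galactolipids, positive-mode
  identification, sn-position and oxylipin structural isomers are out of
  scope; isomers sharing a chain triple are indistinguishable by this
  mass-spectrometric approach.
* RT rules are ordinal constraints, not a retention model; they can flag
  inconsistencies but never confirm a structure.
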