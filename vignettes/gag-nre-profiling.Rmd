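---
title: "GAG non-reducing-end profiling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GAG non-reducing-end profiling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Bacterial lyases (chondroitinase ABC, heparinases II/III) depolymerize CS/DS
and HS by β-elimination. Internal chain segments emerge as disaccharides
whose new non-reducing terminus is a 4,5-unsaturated uronic acid (ΔUA); the
chain's original non-reducing end (NRE) survives as a *saturated* mono-, di-
or trisaccharide. A saturated NRE disaccharide is therefore exactly one
water — 18.0106 Da — heavier than the internal disaccharide of identical
substitution, which is the single mass feature that separates the two pools
at MS1. Reducing ends are labeled with 2-aminobenzamide (2-AB, net addition
120.0687 Da by reductive amination: label − H2O + H2), and ions are observed
in negative mode, optionally as di-n-butylamine (DBA) ion-pair adducts and
with in-source sulfate losses.

`gagnre` models every observable ion species as a composition — counts of
ΔUA, UA, hexosamine backbone units, N-acetyl groups, and sulfates — plus a
charge state, an adduct count and a sulfate-loss count. Key modeling
assumptions:

* **N- and O-sulfation are isobaric** and pooled into a single SO3 count;
  positional identity exists only at the isomer-annotation level (MS2 or
  retention time).
* **GlcA and IdoA are isobaric epimers**; the composition carries a generic
  UA and the epimer lives in the isomer annotation.
* A free-amine glucosamine (GlcNH2, the MPS IIIc hallmark) is a hexosamine
  backbone without N-acetyl and without N-sulfo — no extra mass term.
* The DBA adduct is taken as the neutral amine retained on the deprotonated
  ion, \[M + n·DBA − z·H\]^z−, i.e. +129.1518 Da per adduct before
  deprotonation. The true gas-phase form of the ion pair is not established;
  the constant is isolated in one table so the convention is auditable and
  changeable.
* Charge states are capped at the number of ionizable acidic sites
  (carboxylates + remaining sulfates + the reducing-end/label site, max 4),
  which keeps physically impossible high charges of neutral dp1 species out
  of the catalog.

All monoisotopic constants live in one table (`gag_constants()`); the test
suite checks every ion m/z against an independent elemental-formula
summation and reproduces the diagnostic ions 596.14, 420.11, 337.54,
254.98, 193.04, 175.02 to two decimals.

## The composition database

The searched composition space is configuration, not code: a list of series
(terminus, dp, acetylation range, sulfation range, label state, GAG-class
hint) expanded deterministically by `enumerate_compositions()`. The default
config covers 2-AB-labeled internal dp2 (0–3 SO3, ± N-acetyl), NRE dp1–dp3,
and the *unlabeled* internal disulfated disaccharide (dp2S2) retained as the
labeling-efficiency QC species — 38 records, expanding to 566 ions over
charges, one DBA adduct and sulfate losses.

The assay this package models searched a database of 131 dp compositions,
published only by its size. `inst/extdata/enum_config_synthetic131.json` is
a **synthetic reconstruction** of a database of that size: it spans the
product classes the assay observes (labeled and unlabeled internal di- to
hexasaccharides, NRE mono- to trisaccharides, CS/DS vs HS hints where
isobaric) with bounds chosen so the enumeration totals 131 records. It
exercises the enumeration machinery at realistic scale; it is *not* a
transcription of the unpublished table. The internal dp4/dp6 series
represent incomplete-digestion oligosaccharides, which such search spaces
routinely include even when the generated NREs themselves are dp1–3.

## Matching and consolidation

A feature matches an ion iff |ppm| ≤ 15 (default; the instrument-grade MS1
mass-accuracy gate) and charges agree; features with undetermined charge
(0) may match any charge and are flagged. All candidate matches of a
feature are retained under an ambiguity group; the preferred candidate is
chosen deterministically — smallest |ppm|, then fewer adducts, then fewer
sulfate losses — replacing manual inspection with an auditable rule and a
log.

Sulfate-loss and adduct ions co-elute with their parent. A satellite
candidate is kept only if a parent-species match of the same composition
lies within `rt_tol` = 0.2 min (a generous nano-LC peak width); the
archetypal ambiguity — a disulfated species losing one sulfate and landing
exactly on the mono-sulfated parent m/z — resolves to the loss
interpretation only when the disulfated parent demonstrably co-elutes, and
to the mono-sulfated parent otherwise. Orphan losses with no isobaric
alternative are kept but flagged `loss_only`.

Intensities are summed (not apex-selected) over charge states, attached
adducts and attached losses, per composition and per elution cluster
(single-linkage, 0.2 min gap). Clusters are assigned to named isomers by
nearest reference retention time within 0.25 min; unassignable clusters
keep the composition-level quantity with an `isomer-unresolved` flag rather
than being split heuristically. Intensity is conserved: aggregated plus
unassigned equals the input total (property-tested on randomized trials).

## MS2 isomer rules

The diagnostic fragments and their logic:

* `C1_UA` 193.04 vs `B1_UA` 175.02 — the intact-UA C ion is relatively more
  intense for GlcA-terminated NREs, the dehydrated B ion for
  IdoA-terminated ones. The call thresholds their ratio at 1.0 with a ±20%
  multiplicative dead band returning `unknown`.
* `B1_UA2S` 254.98 present *and* `Y1_HexNAcS_2AB` 420.11 absent — a
  2-O-sulfated uronic acid with unsulfated HexNAc. Both present is reported
  as "mixed" (both residues sulfated) and the strict rule returns `FALSE`.
* The relative abundance of 420.11 separates GalNAc4S from GalNAc6S. The
  *direction* of that difference is demonstrated but not quantified in the
  source assay, so polarity and cutoff are configuration (default: high →
  4S, cutoff 0.30 of base peak, ±0.05 dead band) with
  `calibrate_sulfation()` to set both from standards. **The default
  polarity must be confirmed against standards before any real-data or
  clinical use.**
* GlcNH2 termini (dp3): the precursor mass must require a free-amine
  hexosamine and at least one fragment must retain the terminus (free-amine
  hexosamine C ions 178.07/258.03 by default); mass-only evidence is
  downgraded to `tentative`.

"Absent" means below 1% of the base peak; fragment tolerance is 20 ppm
(MS2 is acquired at lower resolution than MS1). Rules are invariant under
uniform intensity scaling and the epimer call is antisymmetric under
swapping the two UA ions (both property-tested). Candidate structures are
scored +1/−1 per agreeing/contradicted attribute with unknowns neutral; a
unique top scorer with at least one fired rule is `diagnostic`, anything
else `tentative`.

## Quantification

Within-class relative abundances are percentages of the summed labeled
intensity of that class (internal or NRE). The NRE/disaccharide ratio
normalizes each NRE to the combined intensity of the two dominant internal
disaccharides, ΔUAGalNAc4S + ΔUAGalNAc6S ("dp2S1"), which vary far less
across individuals than the NREs; panels operate on this scale. The
GalNAc6S/GalNAc4S ratio and the labeling yield
(labeled dp2S2 / total dp2S2) complete the profile. Undefined ratios (zero
reference, GalNAc4S or the QC pair not detected) propagate as `NA` with a
reason attribute — never as 0 or infinity — because a naive MPS VI sample
genuinely lacks measurable GalNAc6S. Technical replicates are summarized by
arithmetic mean and sample SD, with missing compositions treated as zero
under a warning. The "NRE fraction of all identified saccharides" uses the
same summed aggregation across adducts and charge states as everything
else; that aggregation choice is documented here as the default.

## Biomarker panels

Panels are data, not code: markers, rule kind (presence or ratio),
thresholds, a minimum fired count, and optional control-reference
conditions. Defaults:

| Subtype | Rule | Markers | Threshold |
|---|---|---|---|
| MPS I | presence ≥2/3 | IdoAGlcNS(6S), IdoAGlcNS, IdoAGalNAc4S | >1% of dp2S1 |
| MPS II | presence ≥2/3 | IdoA2SGlcNS(6S), IdoA2SGlcNS, IdoA2SGalNAc4S | >1% of dp2S1 |
| MPS IIIc | presence ≥2/3 | GlcNH2UAGlcNAc(6S), GlcNH2UAGlcNS(6S), GlcNH2(6S)UAGlcNS(6S) | >1% of dp2S1 |
| MPS IVa | ratio | GalNAc6S/GalNAc4S | >0.95 |
| MPS VI | presence + fold | GalNAc4S | >4% of dp2S1, ≥2× control |

The 1% presence threshold encodes "absent or close to the level of
detection in controls"; the MPS IVa cutoff is the control mean + 2 SD
(0.45 + 2·0.25); the MPS VI threshold sits midway between the control level
(~2% of dp2S1) and the three-fold elevation reported for a naive patient
(~6%), because GalNAc4S — unlike the other panels' markers — is present in
every control. MPS I vs MPS II disambiguation rests on the 2-O-sulfated
uronic markers being distinct structures. No numeric "elevated" criterion
exists in the source assay; these are configuration defaults pending
calibration in larger cohorts, and no panels are defined for subtypes
without patient data (IIIa/b/d, IVb, VII, IX). The verdict is the
highest-scoring eligible subtype, ties broken by fired count then panel
order; anything else is "no call".

## The synthetic-data generator

`simulate_sample()` emulates the *statistical structure* of a deconvoluted
feature table: per-structure expected relative intensities, a lognormal
intensity draw per structure (CV 15%) plus an independent lognormal per
feature, a charge-state split over feasible charges (weights
0.55/0.30/0.10/0.05), co-eluting DBA-adduct (15%) and one-sulfate-loss
(10%) satellites, Gaussian m/z error (σ = 3 ppm, ~5σ inside the 15 ppm
gate), Gaussian RT jitter (σ = 0.03 min), a labeled/unlabeled dp2S2 split
at efficiency 0.91, and Poisson decoy features at random m/z. Phenotype
abundance vectors are qualitative transcriptions of the published per-subtype
profiles — which markers are elevated, reduced or absent — anchored to the
printed control statistics (NRE fraction 10.3%, GalNAc6S/GalNAc4S 0.45,
labeling yield 91%, MPS IVa ratio 1.5, MPS VI three-fold GalNAc4S
elevation); bar heights were never printed numerically, so the vectors are
editable config, not data. The naive-MPS VI GalNAc4S weight is set so the
*realized* elevation on the NRE/dp2S1 scale is the documented three-fold,
after accounting for the normalization of the abundance vector.

Retention-time references use the six printed dp2 glycoform retention times
(32.15, 32.66, 33.06, 33.83, 34.86, 37.46 min), which also fix the elution
order IdoAGalNAc4S < GlcAGalNAc4S < GlcAGalNAc6S; all other slots are
plausible synthetic choices spaced ≥ 0.4 min apart within a composition.
MS2 templates encode the qualitative fragment rules above, with the
de-sulfated Y ion anchoring 6S spectra (the 6-O-sulfate is the more labile
in source).

Each phenotype model also records the subtype call the profiler is
*expected* to return: treated MPS VI is modeled as normalized ("no call");
treated MPS I retains reduced but detectable markers (MPS I). Recovery in
the end-to-end tests is measured against these expectations, on
replicate-mean profiles (the assay runs technical triplicates).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: chromatographic peak shapes and RT drift between
runs, isotope envelopes and deconvolution artifacts, urine-dilution and
matrix-effect variance between individuals, epimer-level co-elution
surprises, detector saturation, and any KS-derived products (keratanase
digestion is out of scope). End-to-end recovery on synthetic cohorts
validates the *logic* of the pipeline, not its clinical sensitivity or
specificity.

## Numerical choices and degenerate inputs

* ppm error is signed, `1e6·(obs − theo)/theo`; interval search guards the
  gate boundaries so matching is exact with respect to the brute-force
  all-pairs definition (oracle-tested).
* Matching, consolidation, aggregation and panel evaluation are
  deterministic and order-independent; all tie-breaks are explicit
  (|ppm| → adducts → losses; score → fired count → panel order).
* Empty classes give empty maps; empty peak lists annotate to an empty
  table with a warning; a header-only feature table reads as an empty list
  with a warning; invalid rows are reported by index, never dropped.
* Catalog files round-trip losslessly at 1e-6 Th; import re-derives every
  m/z from the composition fields and rejects inconsistencies and
  duplicate keys with line context.
* Seeds: one integer seed drives a whole simulated cohort; derived seeds
  stay within 32-bit range.

## Problem sizes

The test suite validates matching against a brute-force oracle on 50
random instances up to 50×50, runs 1,000 randomized
monotonicity/conservation trials, recovers the labeling efficiency from
1,000 simulated QC pairs (pooled-ratio estimator, chosen for its
unbiasedness under mean-1 lognormal noise), and measures phenotype recovery
on 20 seeded cohorts of 8 phenotypes × 3 technical replicates. MS2
structure recovery is checked over 9 structure templates × 30 noise
realizations.

## Known limitations

* The 131-entry composition database is a synthetic reconstruction (see
  above); real deployments should import the actual search table.
* The 4S/6S polarity default and all RT references beyond the six printed
  values require calibration against standards.
* Epimer calls from fragment ratios are relative statements; a single
  spectrum without a contrasting standard can remain `unknown`.
* Creatinine normalization, absolute quantification, KS analysis and
  inter-group statistics are intentionally out of scope.
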