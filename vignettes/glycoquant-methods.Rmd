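---
title: "Methods: site-specific glycosylation quantitation and differential calling"
author: "glycoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site-specific glycosylation quantitation and differential calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoquant)
library(dplyr)
```

## The problem and the data model

N-glycosylation is heterogeneous in two directions: one glycosite
carries many glycans, and one glycan decorates many sites. Intact
glycopeptide proteomics preserves the pairing, so the analysis unit is
the *site-specific glycan*: a (protein, glycosite, composition) triple.
`glycoquant` consumes identified glyco-PSM tables — identification
itself (spectral search, FDR control) is upstream and out of scope —
with one reporter-ion intensity per TMT channel, plus a matching
protein-PSM table from the unenriched aliquot of the same labelled
digest.

The default channel design (`hcc_afp_design()`) is the pooled
four-channel tumor/paracancer layout: 126 = paracancer low-AFP,
127N = tumor low-AFP, 128C = paracancer high-AFP, 129N = tumor
high-AFP, with four named comparisons (tumor vs paired paracancer in
each AFP group, tumor low vs high, paracancer low vs high). Because
each group is one pooled channel, there is no replicate variance;
every inferential step is a fold-change rule whose cutoff is justified
empirically by the stability of the paracancer-vs-paracancer null
comparison (`within_fold_fraction()`).

## Glycan composition classification

Compositions are count vectors over HexNAc (N), Hex (H), fucose (F)
and sialic acid (S). Counts alone cannot resolve topology, so the
subtype rules are biosynthetic conventions stated explicitly:

* oligo-mannose: `N == 2`, `H >= 4`, `S == 0` (fucosylated species
  remain oligo-mannose rather than being forced into a core-fucose
  claim that composition data cannot support);
* hybrid: `N >= 3` and `H > N + 1` (an uncapped mannose arm alongside
  GlcNAc-initiated antennae);
* complex: `N >= 3` and `H <= N + 1`;
* pauci/other: everything else (truncated cores such as `N2H3`,
  sialylated `N2` species, degradation products).

These four rules partition all compositions (verified exhaustively for
counts up to 10 in the test suite). For complex glycans the antenna
count is `N - 2`, minus one if the composition is annotated bisecting.
Bisecting GlcNAc and the core/antennary position of fucoses are
structure-level facts: bisecting defaults to `"unknown"` unless an
annotation file is supplied, and the fucose split uses the
first-fucose-is-core heuristic (consistent with the convention of
calling `N4H5F1S1` core-fucosylated) with a per-composition override
table for known antennary-only cases. Monoisotopic mass is the sum of
residue masses (HexNAc 203.07937, Hex 162.05282, dHex 146.05791,
NeuAc 291.09542 Da).

## Normalization and median-ratio quantitation

Channel loading and labelling efficiency differ between channels, so
intensities are normalized with factors derived **from the protein
PSMs only** (the proteome is the stable majority; the glyco-enriched
fraction is not): for each complete protein PSM, each channel intensity
is divided by the geometric mean of that PSM's intensities across
channels, and the factor for a channel is the median of these
scale-free ratios. This construction is exact on constructed inputs
(a channel uniformly scaled by 2 in a 4-channel design gets factor
`2^(3/4)`, the others `2^(-1/4)`) and absorbs any per-channel
rescaling, which the tests verify end to end.

A feature (glycopeptide or protein) is quantified only with at least
`min_psms = 5` complete PSMs — the conventional floor for reporter-ion
ratio reliability; PSMs with any missing/zero channel are excluded from
quantitation but retained for census-style profiling, which uses
identifications only. Each channel value is the **median** of the
feature's normalized PSM intensities, and ratios are ratios of channel
medians. The alternative reading — median of per-PSM ratios — gives
similar estimates on complete PSMs; median-per-channel was fixed
because it yields one channel vector per feature and therefore
composes associatively with any set of named comparisons. One
numerical consequence worth knowing: when between-PSM precursor
scatter is much larger than reporter noise, the per-channel medians
are dominated by the same central PSM, so the ratio variance
approaches that of a single PSM pair rather than shrinking with PSM
count. The estimator stays unbiased (the Monte-Carlo test bounds the
absolute bias of a planted 2-fold change below 0.05 log2 units at 9
PSMs and sigma = 0.25), which is what the fold-change cascades need.

Occupancy changes subtract the parent-protein log2 ratio (matched by
accession; one ratio per protein) from the glycopeptide log2 ratio.
Features whose parent protein fails quantitation get no occupancy value
and are flagged.

## Differential cascades

*Commonly altered*: a feature is `up` if both tumor/paracancer log2
ratios are at least `log2(2)`, `down` if both at most `-log2(2)`.
Discordant features (both beyond the cutoff, opposite directions) are
labelled `none` and flagged `discordant` for separate reporting rather
than silently discarded. Boundaries are inclusive on both sides
(exactly 2-fold counts as changed for the call and as within-band for
the stability fraction); the convention is recorded in the run
manifest.

*Group-unique*: at the reduced 1.5-fold cutoff, a feature is
`lowAFP-unique` if the low- vs high-AFP tumor ratio is at least
1.5-fold **and** the paracancer low-vs-high comparison stays within
1.5-fold at all three levels: glycopeptide ratio, parent-protein ratio,
and occupancy change. The three-level paracancer gate is what rejects
protein-expression differences between patient groups masquerading as
glycosylation differences; features with unquantified parents are
ineligible. No per-feature test statistic exists in a pooled design,
so "significant change" is operationalized purely as these thresholds.

## The synthetic-data generator

`sim_config()` defaults describe the study conditions end to end:
~1,000 glycopeptides (250 glycoproteins, `1 + Poisson(1)` sites per
protein, `1 + Poisson(1)` glycans per site); a 26-composition pool
whose weights give the tissue subtype economy of ~60% complex / 29%
oligo-mannose / 11% hybrid PSM mass with biantennary species carrying
two thirds of the complex weight; negative-binomial PSM counts (mean 8,
size 8 — moderate overdispersion typical of data-dependent
acquisition); log2 baselines spanning roughly four orders of magnitude
(sd 3.3) to stress median robustness; per-PSM precursor scatter of 1
log2 unit; reporter noise sigma = 0.25 log2 units; and unequal channel
loadings (1, 1.25, 0.8, 1.1) that normalization must remove.
Oligo-mannose compositions are preferentially placed on
endomembrane-like proteins (35% of proteins, 3-fold upweighting,
compensated on the remaining proteins so the marginal mix is
unchanged), echoing the ER/Golgi residence of high-mannose glycans.

Planted effect blocks (fractions of glycopeptides): 2.5% common 4-fold
up and 2.5% down (glycopeptide level, both tumors); 3% each low- and
high-AFP-unique 2-fold increases (one tumor channel); 3% protein-driven
4-fold changes — defined as a protein-expression difference between the
patient groups present in both tumor and paracancer tissue, with the
glycopeptide moving along and zero occupancy effect, which is exactly
the confound the paracancer gates must reject; and 2% occupancy shifts
— a tumor-specific 2-fold protein increase with the glycopeptide flat,
visible only at the occupancy level. Ground truth records the label and
the true log2 effect of every comparison at the glycopeptide, protein
and occupancy levels, and the truth table is internally consistent by
construction (`glyco = protein + occupancy`).

What the generator does **not** emulate: identification error and
decoy-level FDR, reporter isotope-impurity spillover between channels,
missing channels, ratio compression from co-isolation, shared peptides
across proteins, and correlated effects between glycans on the same
site. Passing recovery tests therefore demonstrates that the cascades
are correct and well-calibrated under the stated noise model, not that
real acquisitions are free of those artifacts.

`evaluate_recovery()` reports precision and recall per planted label.
Recall is computed over planted features that survived the >= 5-PSM
filter (`n_evaluable`): with negative-binomial PSM counts of mean 8,
roughly 15% of glycopeptides draw fewer than 5 PSMs and are
unquantifiable by the pipeline's own filter, so a recall over all
planted truths would measure PSM sampling rather than the calling
cascades; both denominators are reported.

## Enrichment

The over-representation test is a plain one-sided hypergeometric upper
tail `P(X >= k)` with the background as population — defaulting to the
quantified glycoproteins of the run, not the genome, because the
enrichable universe is what the experiment could have selected. The
retention filter is overlap `>= 3` ("count > 2") and raw `p < 0.05`;
a Benjamini-Hochberg column over all tested terms is emitted for
reference but deliberately not used for filtering, matching the
raw-p convention of the web tools this replaces. Term sets come from
GMT files or named lists.

## Problem sizes and determinism

The test suite and the acceptance script use the default desk-scale
configuration (~1,000 glycopeptides, ~7,500 glyco PSMs, ~7,500 protein
PSMs per run), 1,000-replicate Monte-Carlo loops for estimator bias,
and exhaustive enumeration up to counts of 10 for the classification
rules — sizes chosen so every property is checked in seconds while
leaving no rule unexercised. All randomness flows through explicit
seeds; `simulate_experiment()` is bit-reproducible for a given seed and
restores the caller's RNG state. Result tables are written with
deterministic row and column order alongside a manifest (configuration
hash, seed, package and R versions), so identical inputs give
byte-identical outputs.

## Known limitations

* Composition-level classification cannot see linkage: bisecting
  status and the core/antennary fucose split are annotations or
  heuristics, never inferences.
* No reporter isotope-impurity correction is applied; if correction
  matrices are available they should be applied upstream.
* Parent proteins are matched by accession only; shared-peptide
  protein inference is out of scope.
* The pooled design supports recovery-style validation only — there is
  no replicate-based hypothesis testing or multiple-testing correction
  at the feature level, and the fold cutoffs (2.0 common, 1.5 unique)
  are conventions whose empirical support is the within-fold stability
  of the paracancer null comparison, which should be re-examined on
  any new dataset.
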