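---
title: "From untargeted MS1 features to targeted MS/MS: the pmdda workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From untargeted MS1 features to targeted MS/MS: the pmdda workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmdda)
```

## The problem

An untargeted LC-HRMS full-scan experiment measures thousands of aligned
features (m/z, retention time, per-sample intensity), but most of them are
redundant: a single metabolite typically appears as a protonated molecular
ion plus sodium adducts, isotopologues, in-source neutral losses, oligomers
and other derived signals. Sending every feature to MS/MS is impossible
within the scan-speed budget of one injection, and data-dependent
acquisition fragments whatever is most intense at the moment, which is
often background. The workflow implemented here takes the opposite,
list-driven route:

1. quality-filter the MS1 feature table,
2. collapse redundant ions into pseudo-spectra and elect one precursor ion
   per putative compound,
3. spread the precursor list over as few targeted injections as the
   retention-time density allows,
4. merge the acquired fragment scans into consensus MS2 spectra and link
   them back to the MS1 table,

with cross-polarity feature linking and known-compound matching as
companion steps. Every stage is a plain function over a `feature_table`,
so the pipeline can be re-run, audited and simulated end to end.

## Quality filtering

Three per-feature predicates, applied in any order (they commute):

* **RT range** (`trim_rt_range`): keep `30 s <= rt <= 930 s` by default,
  cutting the void volume and the column wash. Boundaries are inclusive.
* **Blank fold change** (`blank_fold_change_filter`): keep features whose
  mean study intensity is at least 3 times the mean across all pooled
  blank samples. Features absent from the blanks are always kept, which
  makes the rule division-free. The mean (not median, not log) is used
  because with a handful of replicate injections it is the plain reading
  of a fold change between two groups; blanks are pooled rather than
  paired because the emulated design measures five matrix blanks with no
  pairing structure.
* **Replicate RSD** (`rsd_filter`): keep features whose relative standard
  deviation across study samples is at most 30 %. The sample (n-1)
  standard deviation is used, the standard QC convention. Features with
  zero mean are removed.

Both thresholds treat the boundary as passing: a feature at exactly
fold-change 3 or RSD 30 % survives, because the filters remove strict
violators only.

## Redundant-peak reduction by paired mass distances

The core idea is frequency analysis of *paired mass distances* (PMDs):
the absolute m/z difference of two co-eluting features, rounded to two
decimals. A mass relation that is chemical rather than coincidental --
+21.98 for Na/H exchange, 18.01 for water loss, 1.00 for a carbon-13
isotopologue -- recurs across many unrelated retention-time groups, so it
can be recognized from the data alone, without a curated adduct list.
The implementation is a documented reconstruction with these choices:

* **RT grouping** (`assign_rt_groups`): single-linkage clustering on RT
  with a 10 s cutoff. In one dimension this is exactly "break at every RT
  gap larger than the cutoff", which makes the assignment order-independent
  and O(n log n).
* **PMD frequency** (`compute_pmd_frequency`): every within-group pair
  contributes its rounded PMD, but each PMD is counted *at most once per
  RT group*. One compound with many ions therefore cannot inflate a
  distance; frequency counts independent occurrences.
* **High-frequency selection** (`select_high_frequency_pmds`): with no
  explicit cutoff the threshold is placed at the largest drop of the
  descending frequency curve (the elbow), never admitting distances seen
  in fewer than two groups. The elbow avoids a magic constant while
  remaining overridable through `freq_cutoff`.
* **Reduction** (`reduce_redundant_peaks`): within each RT group, features
  are vertices and pairs at a selected PMD are edges; each connected
  component is one putative compound, represented by its *independent
  peak*, the member with the highest mean study intensity (ties to the
  lower m/z).
* **Cluster merging** (`build_and_merge_clusters`): clusters sharing any
  member are unified, keeping the most intense base peak. With components
  produced by the reduction step the inputs are already disjoint and
  merging is the identity; the operation is implemented generically so
  externally constructed, overlapping pseudo-spectra merge correctly.
* **Correlation pruning** (`prune_by_correlation`): ions of one compound
  co-vary across study samples, so members correlating with the base peak
  below r = 0.9 (Pearson, member versus base, across study samples) are
  excluded as co-eluting strangers. The boundary r = 0.9 is retained.
  Pruning needs at least three study samples and removes members whose
  correlation is undefined (zero variance). The member-versus-base
  orientation was chosen over all-pairs pruning because the base peak is
  the cluster's anchor; an all-pairs rule would make membership depend on
  removal order.
* **Precursor election** (`select_precursors`): one target per cluster,
  the member with maximal mean study intensity, ties to the lower m/z.

All mean intensities are arithmetic means over study samples only.
Rounding of mass values that take part in equality comparisons (PMD
binning, two-decimal compound matching) is half-away-from-zero via an
integer centi-Dalton key, so results never depend on the binary
representation of a mass.

## Injection scheduling

Fragmenting several hundred targets in one injection is impossible when
many co-elute, so `schedule_injections` partitions the precursor list
into injections such that within each injection **every sliding RT
interval of 12 s (0.2 min) holds at most 6 targets**. Sliding windows are
the stricter reading of a "retention-time shift" constraint than fixed
bins, and the safer one for the instrument. The algorithm shuffles the
targets with a seed and first-fit places each into the lowest-index
injection that stays feasible. First fit guarantees validity, honors the
random-assignment design, and never needs more than `ceiling(n / 6)`
injections; `validate_plan` re-checks any plan by brute force, and
`export_injection_lists` writes per-injection CSV target lists with RT
windows floored at zero.

## Cross-polarity linking

A compound seen in both ionization modes appears at
`[M+H]+ - [M-H]- = 2 x 1.00728 Da` (electron-corrected) or 2.0157 Da
(plain hydrogen atoms); at two decimals both conventions are the nominal
"2.02". `link_polarities` accepts any positive-negative pair with m/z
difference in `2.0151 +/- 0.011` Da co-eluting within 10 s (inclusive).
The window covers both proton-mass conventions; the center is their
midpoint. A feature may occur in several links, and the linkage is only
meaningful for data acquired on the same column and gradient.

## Consensus MS2 spectra

Targeted MS/MS produces repeated scans per precursor.
`group_scans_by_precursor` assigns scans to targets within 0.02 Da
(nearest target wins, ties to the lower m/z), then
`build_consensus_spectrum` pools the fragments of a target's scans and
clusters them by single linkage at < 5 ppm (ppm always relative to the
smaller of the two m/z values -- stated once because two operations use a
5 ppm bound). A fragment cluster is kept only when observed in **strictly
more than 60 %** of the scans; the kept fragment reports the
intensity-weighted mean m/z and the median per-scan summed intensity.
With a single scan the spectrum passes through unchanged. The 60 % rule
is an *occurrence* filter: the fraction of contributing scans containing
the peak. `link_back_to_ms1` re-attaches consensus spectra (or any
external annotation table with m/z and RT) to MS1 features under strict
< 5 ppm and < 5 s bounds, and `match_known_compounds` compares precursors
against a known-compound mass list as `mass +/- 1.00728` rounded to two
decimals.

## The synthetic study design

`simulate_dataset` generates the ground-truth datasets all recovery tests
run on. It emulates a replicated reference-material design: 5 study
samples, 5 matrix blanks, 300 compounds per polarity each emitting 3 ions
(base plus two offsets drawn from Na adduct +21.9819, water loss
-18.0106, 13C +1.0034), 200 background features, and 30 % of compounds
shared across polarities.

Design points that matter for interpreting test results:

* **Elution bands.** Compound RTs sit on bands spaced 15 s apart (with
  small jitter), mimicking discrete chromatographic peaks. The spacing
  exceeds the 10 s RT-grouping cutoff, so single-linkage grouping
  resolves the bands; features spread uniformly in RT would chain into
  one giant group and defeat per-group frequency counting. Real aligned
  feature tables are also clumped at peak positions, but less regularly:
  this is the main idealization of the generator.
* **Noise model.** Study intensities are
  `abundance x ion ratio x shared factor x ion noise`, all lognormal.
  The shared factor (CV `sqrt(bio_cv^2 + noise_cv^2)`, defaults 0.10 and
  0.05) acts on a whole compound per sample -- extraction, injection and
  spray fluctuations affect all ions of a molecule together -- while the
  independent per-ion noise is small (CV 0.005). This is what makes
  within-compound correlations approach 1 (so r = 0.9 pruning keeps true
  ions) while replicate RSD stays near 11 %, safely inside the 30 % QC
  limit at n = 5. With fully independent per-ion noise no CV could do
  both at five replicates.
* **Background.** Half the background features mirror their blank
  intensities (removed by the fold-change filter), half fluctuate with
  CV 1.5 over zero blanks (removed by the RSD filter).
* **Decoys.** `decoy_fraction` plants features at a high-frequency offset
  from a real base peak but with an independent abundance profile: the
  co-eluting stranger that correlation pruning exists for, exercised near
  its decision boundary.
* **Cross-polarity truth.** Shared compounds differ by 2.0157 Da (small
  jitter) with RT shift below 2 s. Base m/z values are resampled whenever
  an accidental co-eluting cross-polarity pair would fall into the
  linkage window, so the truth map is the complete list of linkable pairs
  and link precision is measurable exactly.
* **MS2 truth.** Each compound carries 5-10 true fragments;
  `simulate_ms2_runs` emits scans with < 2 ppm fragment jitter plus
  single-scan spurious peaks at a configurable rate.

`ground_truth_report` scores pipeline outputs against the truth map:
cluster purity (clusters mapping to one compound), compound recall
(compounds with at least one precursor), precursor correctness
(precursors that are their compound's most intense ion) and link
recall/precision.

What passing these tests shows -- and does not show: the workflow
recovers its own generative model (correlated redundant ions on resolved
elution bands with lognormal noise) essentially perfectly at default
settings. Real data add chromatographic tailing, overlapping peak
shapes, isotope fine structure, intensity-dependent mass error and
adducts outside the offset table; performance there is bounded by how
well those violations respect the same assumptions, not by this suite.

## Numerical choices and degenerate inputs

* Mass rounding for equality tests: two decimals, half away from zero,
  compared on integer centi-Daltons.
* ppm bounds are strict (`< 5 ppm`); intensity/RSD/fold/correlation/RT
  boundaries are inclusive where the rule removes strict violators.
* Ties everywhere break toward the lower m/z, making every stage
  deterministic; the only randomness is the scheduler's seeded shuffle
  and the generator, both funneled through one seed argument with global
  RNG state restored afterwards.
* Degenerate inputs: empty filter results are legal tables; an empty
  high-PMD set makes every feature independent; a zero-fragment spectrum
  is skipped (warning) on MGF export; an mzML file without MS2 scans
  contributes nothing (warning); correlation pruning refuses to act on
  fewer than three study samples.

## Problem sizes used by the test suite

The suite regenerates all fixtures in code: the default 300-compound
simulation (~1100 features per polarity) for end-to-end recovery, 200
random RT groups of up to 12 features against a brute-force
transitive-closure oracle, 100 random precursor sets of up to 2000
targets for the scheduler, and 50 random consensus targets of up to 10
scans x 20 fragments against an all-pairs oracle. The full suite and the
acceptance script each complete in well under a minute on a single CPU.

## Limitations

* GlobalStd-style reduction is reconstructed, not ported: grouping
  method, rounding precision, per-group counting and the elbow rule are
  this package's documented defaults, each overridable.
* The retention-time grouping assumes resolvable elution structure; on
  data whose features chain continuously in RT the per-group frequency
  signal degrades (all pairs fall into few groups).
* Consensus building assumes centroided scans; no centroiding or
  chromatogram extraction is performed.
* Cross-polarity linking is a candidate generator, not an identifier: a
  2.015 Da / 10 s coincidence between unrelated compounds is possible on
  real data.
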