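---
title: "Differential annotation of converted metabolites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential annotation of converted metabolites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dacmet)
```

## The problem

After oral administration of a multi-component preparation — the
motivating case is maoto, a four-herb Kampo decoction (ephedra, apricot
kernel, cinnamon bark, licorice root) — most compounds circulating in
plasma are not the administered molecules. They are *converted
metabolites*: phase-II conjugates formed by the liver and gut wall
(glucuronides, sulfates, glycine/glutamine/glutathione conjugates) and
hydrolysis products of the gut microbiome (e.g. the aglycones of
flavonoid glycosides). These compounds are usually absent from spectral
and compound databases and are prohibitively hard to synthesize, so a
standard database-driven annotation leaves most of the plasma signal
unexplained. `dacmet` annotates them from the structure of the
experiment itself, combining four orthogonal, individually weak lines
of evidence into a defensible assignment.

The input is an aligned LC-HRMS feature table (peaks with m/z, adduct
hypothesis, retention time, and per-sample intensities) plus a sample
design mapping each sample to a class: `pre` (before dosing), `post`
(timed samples after dosing), `mock` (solvent blank), `extract` (the
administered preparation itself), and `herb_plasma` (plasma of animals
given one constituent herb each).

## Differential filtration

A peak is an administration-dependent candidate iff, in order:

1. it is detected in at least `min_samples_detected` samples (default 2);
2. it is never detected in any mock sample;
3. it is never detected in any pre-dose sample of any subject;
4. at at least one post timepoint it is detected in strictly more than
   `post_fraction` (default 0.5) of subjects; and
5. its maximum post-dose intensity reaches `min_ion_count`
   (default 1000 counts).

Rules 2 and 3 are absolute (zero detections, not merely lower
intensity): a converted metabolite has no business appearing in a blank
or before dosing, and absolute rules are robust to the
intensity-dependent missingness typical of peak pickers. "More than
half of subjects at some timepoint" is evaluated per post timepoint
across subjects, which matches a small-cohort design (here 4 subjects
by 6 post timepoints) where a compound's absorption window may cover
only one or two timepoints. The ion-count floor applies to the maximum
across post samples — a peak qualifying at any timepoint is retained.
The intensity column is used as exported by the upstream aligner
(height or area, whichever it produces); the threshold is a parameter
precisely because that convention is upstream of this package.

Every exclusion records its *first failing rule* in a
`filtration_report`, replacing the manual chromatogram review of the
original workflow with a machine-readable audit trail; a user keep/drop
list can re-apply expert judgement on top. Peaks that are alternate ion
forms of one metabolite (opposite ion mode at the same deionized mass,
or a declared adduct/in-source-fragment relation, co-eluting within
`rt_merge_tol` = 0.2 min) are collapsed by `merge_duplicate_ions()`.

## The conjugation network

Every biotransformation shifts the neutral monoisotopic mass by the
mass of the gained (or lost) moiety. The default table
(`default_reaction_table()`) carries the five major conjugations —
glucuronic acid (+C6H8O6, 176.03209 Da), sulfate (+SO3, 79.95682 Da),
glycine (+C2H3NO, 57.02146 Da), glutamine (+C5H8N2O2, 128.05858 Da),
glutathione (+C10H15N3O6S, 305.06816 Da) — plus an "other known
reactions" group for deglycosylation: hexose gain/loss (±C6H10O5,
162.05282 Da) and glucuronide loss (−C6H8O6). The glutathione default
is the net dehydro-GSH delta; the reduced form (+C10H17N3O6S,
307.08381 Da) is available as an option since both conventions occur in
the literature. The table is overridable from TSV or YAML.

`find_difference_pairs()` tests every unordered pair of metabolite
nodes against every delta; the residual of the mass difference is
normalized by the *heavier* mass and accepted at `ppm` (default 5).
Normalizing by the heavier member matches how instrument accuracy
scales and keeps the test symmetric and stable for small deltas.
Matching is intentionally the honest O(n²) enumeration — after
filtration n is in the tens to hundreds, and the test suite holds the
implementation to an independent brute-force oracle.

Two chromatographic layers then discipline the mass-only edges:

* **RT windows.** On a reversed-phase column, adding a polar
  glucuronate or sulfate shortens retention, so those edges must have
  an RT shift (conjugate minus source) in [−3, +0.2] min; other
  conjugations use [−5, +5] min. Windows are closed intervals — the
  permissive reading absent a stated convention. Under this sign
  convention an earlier-eluting conjugate has a negative shift, so the
  windows read directly. Out-of-window edges are *flagged*, never
  deleted: the audit trail survives to the exports.
* **Calibrant scoring.** When several nodes could be the source of the
  same conjugate (typically isomeric aglycones), each candidate edge is
  scored by `|rt_shift − reference_shift|`, the reference being the
  shift measured on a calibrant pair (defaults −1.4 min for sulfation
  and −1.9 min for glucuronidation, from 7-hydroxycoumarin and its
  conjugates). The lowest-scoring within-window candidate is marked
  `preferred`; exact ties stay flagged `ambiguous` rather than being
  resolved arbitrarily.

Nodes are metabolites, not raw peaks: duplicate-ion merging and
co-elution merging precede edge finding, so one compound observed in
both ion modes is one node (e.g. `P8722/N6061`-style joined ids). The
ephedrine/pseudoephedrine pair — isobaric stereoisomers 0.15 min apart —
is the canonical entry of the never-merge exception list.

Herbal origin is overlaid by presence in the single-herb animal plasma
samples; multi-origin nodes are kept and flagged, not resolved, because
the network itself cannot distinguish a shared constituent from a
coincidence. Connected components over within-window edges become
subnetworks, labelled deterministically (descending size, then
ascending smallest mass) — the labels are bookkeeping, not chemistry.

## Orthogonal evidence and MSI levels

* **³⁴S isotopologue** (`detect_34S()`): sulfur shows a natural
  isotopologue +1.99580 Da above the monoisotopic peak at 4.25% per
  sulfur atom. The offset tolerance (0.01 Da) is narrow enough to
  exclude the ¹³C₂ isotopologue at +2.00671 Da; the accepted per-sulfur
  intensity band (2–8%) tolerates ion-statistics noise. The sulfur
  count is estimated as the rounded ratio to 4.25%. An absent pattern
  is *no evidence*, never counter-evidence.
* **Diagnostic neutral losses** (`detect_neutral_loss()`): a fragment
  `precursor − fragment ≈ 79.95682` (NL-80) marks a sulfate,
  176.03209 (NL-176) a glucuronide, 162.05282 a hexoside. The default
  fragment tolerance is 0.5 Da because ion-trap CID spectra are the
  common acquisition for the fragmentation scan event; 0.01 Da suits
  high-resolution MS/MS. The precursor−fragment difference is used
  directly (rather than a stepped neutral-loss scan), which is what an
  MGF peak list supports.
* **MSI levels** (`assign_msi_level()`): an explicit rubric replaces
  expert judgement — level 1 needs an authentic-standard match on mass
  (≤5 ppm) and RT (≤0.2 min); level 2 needs a network edge with a
  preferred source plus at least one orthogonal line (³⁴S, neutral
  loss, or calibrant-shift agreement within 0.5 min); level 3 a
  database/literature annotation; level 4 a formula only. The rubric is
  monotone: adding evidence can only improve a level, and missing
  spectra never downgrade below what the network supports. Positional
  isomers (which glucuronidation site) are out of scope — that genuinely
  requires synthesized standards.

## Kinetic time courses

Per-metabolite time courses over (subject, timepoint) columns are
imputed with the row half-minimum (missing means "below detection", so
half the smallest observed value is a conservative stand-in), then
auto-scaled to row mean 0 and standard deviation 1 using the sample
(n−1) standard deviation — the "standard deviation of the mean" wording
that sometimes accompanies auto-scaling is read as the ordinary row
standard deviation, since the standard error would not yield
unit-variance rows and auto-scaling is the named procedure.
Clustering is agglomerative with Ward's criterion on Euclidean
distances (`hclust`, `ward.D2`, whose merge heights are provably
non-decreasing). The flat cut (`k`) is a user parameter; no canonical
cluster count exists for such data. `coclustering_report()` then asks,
per within-window edge, whether conjugate and source share a flat
label: host conjugates should co-cluster with their sources, while
microbiome hydrolysis products (deglycosylation edges) are *expected*
to lag by hours and fail the check — agreement there would be
suspicious, not reassuring.

## The synthetic experiment generator

No public dataset accompanies the motivating study, so validation rests
on `generate_fixture()`, which emits a complete experiment in the
package's canonical formats: 4 subjects sampled pre-dose and at 0.25,
0.5, 1, 2, 4 and 8 h, two solvent blanks, one extract sample, and one
rat plasma sample per herb. The default compound set plants ten source
metabolites of the four herbs and ten conjugates with
reversed-phase-plausible shifts, log-normal-shaped time profiles
(early ephedrine analogues, late licorice metabolites, delayed
aglycones), subject-level amplitude variation, a detection limit of
500 counts, and five decoy classes designed to die on specific
filtration rules (blank contaminants, pre-dose background, singletons,
sub-threshold peaks) or to survive legitimately (delta-free random
masses, rejection-sampled so that no pairwise difference mimics a
reaction within 25 ppm). Sulfate conjugates receive a ³⁴S isotopologue
and an NL-80 fragment; everything gets a ¹³C isotopologue.

Numerical choices worth stating explicitly:

* **Mass jitter is clipped.** Observed masses get Gaussian ppm noise
  (default sd 2 ppm) truncated at 2 sd, and a conjugate's jitter is
  applied relative to its *observed* source mass. Both choices reflect
  how calibrated high-resolution instruments behave: mass error is
  bounded by calibration, and errors within one run are strongly
  correlated, so the error of a mass *difference* is much smaller than
  two independent per-peak errors. An unbounded independent-error model
  at the same nominal ppm would be dominated by its tails and would not
  represent a calibrated instrument.
* **RT jitter** (default sd 0.1 min, clipped at 2 sd) perturbs the
  planted shifts, keeping glucuronide/sulfate shifts inside their
  windows as in real reversed-phase data.
* **Determinism.** All randomness flows from one seed; the generator
  saves and restores the global RNG state, and a fixed seed yields
  byte-identical files.

The licorice preset (`subnetwork_a_spec()`) is noise-free and plants
the glycoside → aglycone → conjugate family with the conjugates 1.3
and 1.7 min before liquiritigenin and hence 2.8 and 3.2 min before
isoliquiritigenin — so the RT window plus calibrant scoring, and
nothing else, decides which isomer is the source.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: chromatographic peak-shape quality and the
false positives/negatives of upstream peak picking, co-eluting isomer
interference beyond the planted pairs, ion suppression, adduct
diversity beyond ±H, and real pharmacokinetic shapes beyond a
log-normal bump. Results on real tables will be limited by the aligner
feeding the package, which is exactly why the filtration report keeps a
per-peak audit trail.

## Validation problem sizes

The test suite works at sizes chosen to exercise every code path while
staying comfortable on one CPU: property checks over dozens of random
tables; oracle equivalence of pair finding on 200 random 50-node
instances; and a 100-seed study of the default synthetic experiment
(about 55 peaks by 35 samples each) through filtration and network
construction, on which planted-peak recovery is complete and planted
pair-relation recall exceeds 0.99 — the residual misses are
cross-family relations whose two endpoints carry independent mass
jitter. Those same quantities are recomputed, not quoted, by the test
suite on every run.

## Known limitations

* Direction of a mass relation is chromatographic/biological, not
  spectral: a pair matching glucuronidation also matches glucuronide
  loss, and only RT behaviour and kinetics argue which way the
  chemistry ran.
* Coincidental delta matches among unrelated compounds are irreducible
  at 5 ppm in dense tables; the within-window flag, calibrant score and
  co-clustering report are the tools to triage them, not a reason to
  delete edges silently.
* The package consumes aligned feature tables; peak detection,
  alignment and compound-database search are upstream concerns by
  design.
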