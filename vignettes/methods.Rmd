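---
title: "Methods: post-metabolic activity screening with TDCscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-metabolic activity screening with TDCscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TDCscreen)
```

TDCscreen evaluates whether hepatic metabolism changes the
endocrine-disrupting activity of a chemical. The workflow couples three
measurement modalities: an in vitro metabolic reaction (liver S9 fraction,
with cofactors enabling phase I or phase I+II enzymes), LC-MS/MS profiling
of the reaction products against an inactive-enzyme control, and a
luciferase reporter assay for thyroid-hormone-receptor (THR) transcriptional
activity. This vignette documents the models, parameters and numerical
choices behind each computational stage, and what the synthetic test bed
does and does not establish.

## Biotransformant prediction

A metabolic reaction is modelled purely as a signed elemental-composition
delta: glucuronidation adds C6H8O6, sulfation adds SO3, oxidative
dechlorination swaps Cl for OH, and so on. The shipped library
(`defaultTransformations()`) contains 19 phase I functionalization reactions
and 9 phase II conjugations; it is a YAML file users can extend.

Candidate biotransformants of a parent formula are generated by
`enumerateBiotransformants()` as all element-wise sums over unordered
*multisets* of library reactions, bounded by `maxTotal = 5` total steps and
`maxPhase2 = 1` conjugation. Two consequences of treating paths as
multisets rather than sequences:

* accurate-mass matching cannot distinguish reaction order, so ordered
  variants of one multiset would be pure duplication — one canonical
  representative path (fewest steps, then lexicographically smallest) is
  stored per distinct product formula;
* validity is decided on the final product only: any product with a
  negative element count is pruned. This automatically restricts
  dehalogenations to halogen-bearing parents (a mono-iodo parent can lose
  exactly one iodine) without a compound whitelist.

The depth limits matter: the default library at depth 5 yields on the order
of 1e4 distinct product formulas for a drug-sized parent, enumerated from
roughly 1e5 reaction multisets in a few seconds (results are memoised per
parent/library/depth). Masses come from an embedded table of
most-abundant-isotope masses; adduct m/z is neutral mass ± 1.007276
(proton), singly charged only — multiply charged species and adducts other
than (de)protonation are out of scope.

## Feature annotation and fragment coverage

`matchFeatures()` pairs observed feature m/z with predicted adduct m/z at a
relative tolerance of **5 ppm** (MS1, inclusive at the boundary), keeping
every match when isobaric predictions collide and flagging the ambiguity
rather than guessing. Features matching the same prediction are grouped by
single-linkage on retention time with a **0.1 min** tolerance.

MS2 support is scored by `fishCoverage()` under a shifted-fragment model:
the candidate fragment set is the parent's centroids plus each centroid
shifted by the reaction-delta mass (for multi-step paths, each cumulative
partial-sum shift can be added via `steps`). Coverage is the percentage of
feature centroids above a signal-to-noise floor that match any candidate
within **10 ppm**. This is a deliberate formula-level approximation: no
bond-level in-silico fragmentation is attempted, so rearrangement fragments
are invisible to the score. The S/N floor is **3 × the median centroid
intensity** of the feature spectrum — a spectrum-internal noise proxy,
because centroided MGF files carry no per-scan noise estimates. Degenerate
case: in a perfectly flat spectrum no centroid exceeds 3 × median; the
implementation then scores all centroids rather than returning 0/0. A
feature without MS2 has *no* coverage score (`NA`), never a zero.

The merge filter keeps an annotation when maximum per-sample area reaches
**1e5** counts *or* coverage reaches **50%**; both criteria are recorded
per record. The area threshold is read as 1×10⁵ on the feature's maximum
per-sample area: with a 10,000-count detection floor upstream, any
materially lower threshold would be vacuous.

## Molecular networking

`modifiedCosine()` square-root transforms intensities (damping the dominant
base peak, the common networking convention) and normalizes each spectrum to
unit vector norm. A peak pair is eligible if the fragment m/z agree within
**0.05 Da** directly, or after offsetting by the precursor mass difference —
the channel that lets a conjugate's shifted fragment series match its
parent. A one-to-one matching is chosen greedily by descending pair score;
with a 0.05 Da tolerance eligible pairs are sparse and the greedy matching
coincides with the exhaustive optimum (the test suite verifies agreement to
1e-9 on a thousand random small spectra, and stress-tests the greedy choice
under deliberately congested tolerances).

`buildNetwork()` admits an edge when cosine **> 0.5** (strict), matched
ions **≥ 6**, and |precursor shift| **≤ 500** m/z, then applies *mutual*
top-K pruning with **K = 10**: an edge survives only if both endpoints rank
it within their 10 best edges by cosine (ties broken by partner id, so the
graph is reproducible). Single-sided retention is available via
`mutual = FALSE`. The strict/inclusive reading of "more than 0.5" / "6
matched ions" follows the de facto networking defaults; both are plain
arguments. Components are computed with igraph on surviving edges;
`componentSummary()` reports all components and flags those with more than
10 nodes for the headline table. `annotateSubnetwork()` then tests every
node of the parent's component against the predictions at 5 ppm; unmatched
neighbors are reported as candidate-novel with their Δm/z from the parent —
that is the mechanism by which biotransformants outside the reaction
library (e.g. products of unanticipated reactions) surface as leads.

Chemical-class labels for nodes are accepted as optional metadata
(`writeNetwork(nodeData = ...)`) and never computed: class annotation
services are web workflows, out of scope here.

## Statistics

Areas are imputed per feature with **10% of the minimum observed area**
of that feature across samples (the per-feature reading of the
minimum-imputation rule; a global-minimum variant would couple unrelated
features). Observed values are never altered, and features observed nowhere
are dropped.

Fold change is mean(reaction)/mean(control); the parent's metabolic rate is
100 × (1 − FC), signed, so a parent that *increases* after reaction gets a
negative rate.

`mannWhitney()` is two-sided. By default it enumerates the exact
permutation distribution whenever the pooled sample size is ≤ 12 (at n = 3
vs 3 that is 20 assignments) and otherwise uses the tie-corrected normal
approximation with a continuity correction. A caveat worth stating plainly:
at n = 3 per arm the smallest exact two-sided p-value is 0.1, so **no
feature can be significant at α = 0.05 under the exact test at this design
size**. Screening pipelines that report p < 0.05 asterisks at n = 3 are
implicitly using the uncorrected normal approximation, whose smallest
attainable p at complete separation is 0.0495 — at the price of a 10%
type-I error at the 5% nominal level. Both behaviours are available
(`method = "normal", continuity = FALSE` reproduces the asterisk-style
call); the package default stays with the exact test, whose size is honest,
and the volcano classification (`up`: FC > 1 and p < α; `down`: FC < 1 and
p < α; else `ns`) takes whichever p-values it is given. No multiplicity
correction is applied by default, matching screening practice;
`volcanoTable(fdr = TRUE)` switches on Benjamini-Hochberg.

## Reporter assay

Relative transcriptional activity anchors each plate internally:

RTA = 100 × (test − mean VC_test) / (mean PC − mean VC_control),

where VC_test is the vehicle control of the test well's own treatment arm
(S9 mixtures themselves shift baseline luminescence; anchoring each arm to
its own vehicle removes that). RTA is computed per replicate and then
summarized (mean, SD by default, SEM optionally, n), so the reported spread
reflects replicate scatter after normalization. The normalization is exactly
invariant to affine gain changes of the reader. A compound/arm is
**agonist-positive when RTA ≥ 10% of PC at any dose** (inclusive at 10.0).
A plate whose PC and VC are indistinguishable is an invalid assay (error,
not a number); a configurable PC/VC fold-induction QC warning (e.g. 4.8×)
is available but not enforced, since it is a plate-quality observation
rather than a hard gate. Dose-response curves are deliberately not fitted —
activities are reported per dose, and the positivity rule needs no EC50.

## The synthetic test bed

`simulateExperiment()` emulates the statistical structure of a
one-compound screening experiment, not its chemistry or chromatography:

* a triiodothyronine-like parent (C15H12I3NO4, positive mode) with a 3%
  true metabolic rate; n = 3 replicates per arm; log-normal multiplicative
  area noise with CV 0.2;
* five planted biotransformants (glucuronide, sulfate,
  oxidation+glucuronide, deiodination, glutathione) at log2 fold changes
  3, 2.5, 2.2, 2, 2 — the conjugation-dominated pattern typical of
  THR-active compounds — placed at their predicted m/z perturbed uniformly
  within ±3 ppm (inside the 5 ppm gate; a 6–10 ppm near-miss mode exists
  for negative tests);
* 50 decoy features rejection-sampled to sit ≥ 20 ppm from *every*
  predicted m/z, with random MS2 spectra;
* transformant MS2 = parent fragments shifted by the net delta mass plus 3
  random noise fragments; 12 fragments per spectrum;
* plates with PC/VC anchors and four arms following a saturating
  dose-response (EC50 1e-8 M over doses 1e-9–1e-5 M), top-dose activities
  100/100/150/309.1% of PC for parent / inactive-S9 / phase I / phase I+II,
  Gaussian noise at 2% of the PC−VC window.

What passing tests on this bed establish: the pipeline's bookkeeping is
correct end to end — planted signals inside the tolerances are recovered,
placed in the parent's component and correctly path-annotated, and decoys
are never annotated. What they do not establish: performance on real data,
where isotopologues, in-source fragments, co-eluting isomers, adduct
multiplicity, chromatographic peak-shape pathologies and library-incomplete
chemistry all occur and are explicitly not simulated.

Problem sizes in the shipped tests were chosen to exercise every code path
while keeping the suite quick: exhaustive enumeration oracles run at
library ≤ 4 / depth ≤ 3, the matching oracle at ≤ 6 peaks × 1,000 pairs,
the null-calibration simulation at 10,000 features, and end-to-end recovery
at 20 seeds × (1 parent + 5 planted + 50 decoys).

## Known limitations

* Products are formula-level; positional isomers collapse to one candidate
  and structure proposal is delegated to external tools via the notes
  fields.
* The fragment-coverage score is an approximation of proprietary
  fragment-ion-search scoring; absolute values are not comparable across
  software, only the ≥ 50% filter semantics.
* One polarity per run; no mixed-mode merging.
* Greedy (not globally optimal) QC alignment and peak matching; both are
  deterministic and tested against exhaustive oracles at small sizes.
* The reaction library is a flat list of deltas: no reaction-site logic, no
  enzyme kinetics, no sequential-feasibility constraints beyond elemental
  accounting.
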