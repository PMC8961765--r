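---
title: "Gene-specific missense pathogenicity models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-specific missense pathogenicity models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prospr)
```

## The problem and the modelling stance

Missense variants in clinically tested disease genes are interpreted
against cohorts that are strongly skewed: databases of disease-associated
variants on one side, population variants on the other. A single
genome-wide model blurs gene-to-gene differences in which protein
properties matter. `prospr` instead fits one small classifier per gene
on that gene's own labelled variants, and separately asks whether
external predictor scores become more useful when their pathogenicity
cut-off is tuned per gene.

Two assumptions follow from this stance. First, per-gene sample sizes
are modest (tens to hundreds of variants), so the classifiers are
deliberately low-capacity and every numeric feature is discretised into
a handful of nominal bins before training. Second, the two cohorts are
treated as class-skewed samples rather than unbiased draws: class
balancing reweights instances so both classes carry equal total weight,
and all probabilities are calibrated on that balanced distribution, not
on any population prevalence.

## The feature catalogue

`feature_catalogue()` fixes 22 features per variant. The catalogue mixes
*general* features computable for every gene (physicochemical changes,
conservation, accessibility, goodness-of-fit) with *gene-specific* ones
that exist only where annotations or structures do (domains, topology,
functional sites, variant clustering). Missingness is always explicit:
a variant at a position absent from the structural model keeps its
sequence features and gets missing markers for every structure-derived
feature, and the classifiers treat "missing" as its own category rather
than imputing silently.

Choices worth recording:

- **Residue volumes** are the Richards-scale values embedded as a
  constant table; the volume-change category uses a ±40 Å³ cut-off,
  roughly one CH₂-rich side-chain step. Because downstream supervised
  discretisation re-bins the signed volume change anyway, model
  behaviour is insensitive to the exact cut-off; the category mainly
  serves interpretability.
- **Strong hydrophobicity** uses the seven-residue set
  {V, I, L, F, M, W, C}, configurable through
  `residue_property_table()`, since hydrophobicity scales differ at the
  margins (notably C and W).
- **Charge change** (positive/negative/neutral class switch) is included
  so that the physicochemical block covers size, hydrophobicity and
  charge; H is counted positive.
- **Clustering** of pathogenic variants is computed both in sequence
  (±5 residues) and in space (Cα–Cα within 8 Å). No published
  definition pins these numbers; 8 Å is a common contact-shell radius
  and ±5 spans one or two turns of secondary structure. Both counts are
  leave-one-out: a variant's own record never contributes to its count,
  otherwise the feature would encode the label it is supposed to
  predict.

## Solvent accessibility

Side-chain accessibility uses the Shrake–Rupley sphere-point method
(probe 1.4 Å, 256 points per atom by default, Fibonacci lattice) over
all side-chain atoms (Cα for glycine), normalised by the same residue's
side-chain accessibility in an extended Ala-X-Ala tripeptide and
reported in percent, following the Naccess convention of *relative*
side-chain accessibility. Values above 100% are possible and kept.

Three numerical decisions matter here:

- **Self-consistent reference state.** The tripeptide reference areas
  are not copied from published tables; they are computed once per
  session by the package's own backbone generator and SASA engine and
  cached. This guarantees that numerator and denominator share one
  representation — important because the synthetic structures carry a
  reduced side chain (a single Cβ pseudo-sphere whose radius derives
  from the residue's volume), not full atoms. For full-atom input the
  same code path runs on all side-chain atoms; parity with any specific
  Naccess build is not a goal.
- **Exact rigid-motion invariance.** Sphere-point methods are not
  natively rotation-invariant (the lattice is fixed in space). All SASA
  computations therefore run in a canonical molecular frame anchored on
  the structure itself (centroid, first atom, and the least-colinear
  atom), so any rigid transform of the input yields bit-identical
  values.
- **Boundary anti-aliasing.** Points near an occluder's surface flip
  in/out as the point count changes. A linear transition band of half a
  lattice spacing replaces the hard indicator, which is unbiased to
  first order and makes values stable to well under 2 percentage points
  when the point count doubles; 256 points then suffice.

Burial bins follow common relative-accessibility practice: buried
< 9%, intermediate 9–36% (right-closed), exposed > 36%; both edges are
configurable. The secondary-structure fallback (used only when no
annotation track is supplied) assigns H to runs ≥ 4 of φ ∈ (−100°, −30°),
ψ ∈ (−80°, −5°) and E to runs ≥ 3 of φ ∈ (−180°, −80°), ψ ∈ (60°, 180°);
it is intentionally a cartoon-level assignment, not a hydrogen-bond
method, because it stands in for a visualisation tool's assignment, and
strand windows are checked before helix windows so the rare overlap
resolves to the stricter run requirement.

## Preprocessing filters

**Class balancing** multiplies each minority-class weight by
N(majority)/N(minority), leaving the majority at weight 1, so both
classes total N(majority): 20 pathogenic vs 80 benign gives pathogenic
weight 4 and totals 80/80. This follows the filter's worked-example
contract rather than the alternative convention of rescaling both
classes to N/2; the two differ only by a global scale, which none of
the classifiers is sensitive to, but the worked example is the contract
we pin.

**Supervised discretisation** is Fayyad–Irani recursive binary
splitting on weighted class entropy with the MDL stopping rule: a cut
is accepted only when its information gain exceeds
(log₂(N−1) + log₂(3ᵏ−2) − k·Ent(S) + k₁·Ent(S₁) + k₂·Ent(S₂)) / N.
Candidate cuts are midpoints between adjacent distinct values; applied
bins are right-closed below (x ≤ cut → lower bin), values beyond the
fitted range join the end bins, and missing values form their own
category. Constant columns and columns whose root split fails the MDL
test get a single bin.

**Leakage discipline.** Both filters are fitted inside each
cross-validation training fold and merely *applied* to the held-out
fold. The alternative — fitting the discretiser once on the full
dataset — looks harmless but lets held-out labels shape the cut points;
on small cohorts of pure noise this inflates cross-validated MCC from
≈ 0 to ≈ 0.3 (the test suite demonstrates exactly this with a
deliberately global mode that exists only for that demonstration).
Whether the original batch-toolkit workflow applied the filters before
or inside CV cannot be determined from its description; we implement
the leak-free reading.

## The three classifiers

All three respect instance weights (duplicating an instance is
equivalent to doubling its weight) and are deterministic given row
order and seed.

- **LogitBoost over decision stumps** (default M = 10 iterations):
  working responses z = (y − p)/(p(1−p)) with p clamped to
  [10⁻⁵, 1−10⁻⁵] and z capped at ±3; case weights w·p(1−p); one
  weighted least-squares stump per iteration; F ← F + ½f; p =
  1/(1+e^(−2F)). Stumps split numeric columns at value-run boundaries
  and route missing values to their own branch.
- **Simple logistic**: the same boosting loop with single-attribute
  linear regressions as base learners, the iteration count chosen by an
  internal stratified 5-fold cross-validation of the error rate
  (earliest minimum on ties, up to 50 iterations), then refit at that
  count; the model collapses to per-attribute coefficients on
  standardised inputs with missing values zero-imputed after
  standardisation.
- **Hoeffding tree**: the dataset is streamed once in input order;
  a leaf splits when the information-gain lead of the best attribute
  exceeds ε = √(ln(1/δ)/(2n)) with δ = 10⁻⁷ and n the weighted count at
  the leaf, or when ε drops below the 0.05 tie threshold; checks happen
  every 200 weighted instances (the grace period); leaves predict
  Laplace-smoothed probabilities. Numeric attributes are pre-binned
  into at most 10 weighted quantile bins at the start of the fit — a
  batch-wrapper convention that keeps the streaming core purely
  categorical. On cohorts much smaller than the grace period the tree
  never splits and predicts the class prior; that is faithful to the
  algorithm's defaults, and algorithm selection simply passes it over
  for such genes.

These parameter values are the named algorithms' canonical defaults,
pinned here explicitly because "default parameters" of a toolkit are
otherwise unreproducible. Numeric parity with any particular toolkit
build is not a goal.

## Evaluation and selection

MCC is computed from the confusion matrix pooled across the k folds of
each repeat (not averaged over folds — the two differ whenever a fold
is degenerate), with the 0/0 convention MCC = 0 when a denominator
factor vanishes; the SD is across repeats. ROC AUC uses the
Mann–Whitney identity with half-credit for ties; PR AUC uses the
average-precision convention with tied scores grouped. Algorithm choice
is argmax of mean MCC with fixed precedence (logitboost >
simple_logistic > hoeffding_tree) on exact ties, so reruns cannot
flip-flop. Feature selection is greedy backward elimination visiting
features in ascending |Pearson r| with the class; a drop is kept when
the repeated-CV MCC does not fall by more than 10⁻⁹. This is a
reproducible automation of a manual exclude-and-check workflow;
exhaustive subset search over 2²² candidates is out of the question.
Group-level score comparisons use the rank-based Kruskal–Wallis test
(chi-square approximation, tie-corrected) and the Wilcoxon signed-rank
test (exact for ≤ 25 untied non-zero differences, normal approximation
with continuity correction otherwise); both delegate to R's stats
implementations behind the package's interface.

## Gene-specific thresholds

The score grid is {0, 0.05, …, 1} — 21 uniformly spaced candidate
thresholds. Classification is *score ≥ t* (the ≥/>
choice is a convention; ties in MCC break toward the lowest qualifying
threshold, which under separation yields the lowest grid point strictly
above all negative scores). Per repeat (n = 10) of a stratified
five-fold split, the best threshold on each 80% training split is
evaluated on the held-out 20%; the *optimised MCC* is the mean of the
50 held-out values and the reported *gene-specific threshold* is the
median of the 50 training optima (an aggregation rule we fix because a
single per-gene threshold must be reported; the mean is more
outlier-sensitive at grid edges). The *default MCC* is computed on the
full cohort at the tool's default threshold. Degenerate folds (a class
missing from train or test) trigger a reshuffle of that repeat with a
shifted seed, up to ten times. The balanced mode undersamples the
majority class (uniform, without replacement, seeded) before the
search; with a high-scoring pathogenic majority this removes the
downward pull on the MCC-optimal threshold, so balanced thresholds sit
higher on average — the direction the per-gene optimisation literature
reports.

## What the generator emulates — and what it does not

`simulate_gene_panel()` produces 21 genes with pathogenic counts drawn
from 70–600 and benign from 15–200, matching the imbalance envelope of
real per-gene cohorts (the 70-variant floor mirrors the usual minimum
for training per-gene models). Default protein length is 240 residues
with the C-terminal 20% left unmodelled, so the modelled/unmodelled
dichotomy is always exercised. Pathogenic variants favour highly
conserved (grade 8–9) and buried positions through a class-conditional
mixture (`p_high_cons`, `p_buried`, defaults 0.9/0.2 and 0.6/0.15
pathogenic/benign) and drastic substitutions (|ΔV| > 40 ų with
probability 0.5 vs 0.15); stability/PPI tracks co-vary with
conservation. External scores are class-conditional Beta draws whose
density-crossing point is recorded analytically as the ground-truth
threshold. Setting both classes' parameters equal produces a genuine
null dataset, which the test suite uses for calibration checks.

The generator targets *statistical* structure, not biophysics: no
mutation spectrum, no real energetics, reduced side chains, idealised
backbones and a single chain. Passing tests therefore demonstrate that
the pipeline recovers class-conditional feature structure at realistic
sample sizes and imbalance — not that it reproduces any particular
clinical cohort, whose label noise, annotation errors and feature
correlations are outside the generator's vocabulary.

## Problem sizes and reproducibility

The shipped tests and the acceptance script size their simulations to
keep a full run in the minutes range on one CPU: repeated CV uses 2–3
repeats where the defaults are 10, the feature-subset search uses one
repeat of 5 folds during end-to-end runs, and oracle comparisons use
instances of at most a few dozen points (where brute force is exact).
The defaults exposed by the functions (10×10-fold CV, 10×5-fold
threshold search) remain the recommended settings for real analyses.
Every entry point takes an integer seed; repeated runs with the same
seed are bit-identical, which the manifest hash in
`write_manifest()` makes checkable.

## Known limitations

- PDB residue numbering is assumed to match protein positions up to a
  constant offset (`residue_offset`); mapping variants onto structures
  with non-trivial renumbering or non-canonical transcripts is the
  caller's responsibility.
- Single chain only; inter-chain burial and interface effects are
  invisible.
- Conservation, disorder, stability and interaction scores are consumed
  as input tracks, not recomputed; upstream curation rules (e.g.
  restricting benign sets to hemizygous observations) are documented
  conventions of the input, not enforced by the package.
- Probabilities are calibrated on the balanced training distribution;
  they are rankings with a 0.5 decision point, not population
  posteriors.
- The Hoeffding tree is included for contract completeness but rarely
  wins on cohorts below a few hundred variants, by construction of its
  grace period.
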