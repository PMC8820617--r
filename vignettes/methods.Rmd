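---
title: "Methods: structure- and ligand-based CYP2C9 inhibition modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure- and ligand-based CYP2C9 inhibition modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypscreen)
```

## The modeling problem

Cytochrome P450 2C9 (CYP2C9) metabolizes roughly one drug in seven;
molecules that inhibit it are a common cause of drug--drug
interactions. `cypscreen` implements a complete pipeline for building
binary inhibitor / non-inhibitor classifiers that combine two kinds of
evidence:

* **ligand-based descriptors** — 2D/3D physicochemical properties of
  the molecule itself, and
* **structure-based descriptors** — docking interaction energies (IEs,
  kcal/mol) of the molecule against an ensemble of seven receptor
  conformations: the 1R9O and 5XXI crystal structures and five
  molecular-dynamics-derived conformations (MD1--MD5). Docking itself
  is external; the package manages job bookkeeping, parses engine
  output, and consumes IE tables.

The trained random-forest (RF) and RBF-kernel support-vector (SVM)
classifiers are combined into a *consensus*: a screening candidate is
carried forward only when both models call it an inhibitor, and is
*prioritized* only when, additionally, its IE against **every** one of
the seven conformations is strictly below a cutoff (default
−8.5 kcal/mol). Prioritized hits are then diversity-clustered in two
stages and one (or, for large clusters, several) representatives per
cluster are proposed for experimental follow-up.

## Dataset curation

Activity records are labeled by two rules: a compound with an AC50 (or
IC50) of at most 10 µM is an **inhibitor** (boundary inclusive); a
compound showing less than 10% inhibition at 50 µM, with no qualifying
AC50, is a **non-inhibitor**; anything else is *ambiguous* and is
excluded from modeling. A record satisfying both rules at once is
contradictory assay evidence and raises an error rather than being
silently resolved.

The **soft drug-like filter** keeps the applicability domain broad:
MW ∈ [100, 800] Da, logP ∈ [−4, 8], ≤ 7 H-bond donors, ≤ 14
acceptors, ≤ 20 rotatable bonds, TPSA ≤ 250 Å². These bounds are
deliberately looser than Lipinski-style rules — reactive or
PAINS-flagged chemotypes can still be CYP inhibitors, so no
toxicophore/PAINS removal is performed (and none is implemented).
Every bound is configurable through `filter_config()`; rejected
records carry the full list of violated rules.

Duplicates are collapsed on Open Babel canonical SMILES. Duplicates
agreeing on the label merge their provenance; duplicates with
conflicting labels are **dropped entirely** and logged — injecting a
coin-flip label would add noise exactly where the evidence is worst.

**Diversity clustering** uses leader (sphere-exclusion) clustering:
every member is within the Tanimoto cutoff (default 0.85) of its
cluster centroid and centroids are pairwise below the cutoff.
Processing order is descending neighbour count with ties broken by
ascending id, which makes the partition deterministic. The original
procedure used a proprietary fragment fingerprint inside a commercial
desktop tool; this package substitutes open Open Babel fingerprints — a
path-based fingerprint (FP2, 1024 bits) and a 166-key structural-key
set (MACCS) — and records the fingerprint kind with every cluster
assignment. Cutoffs are kept at their published values; only the
fingerprint implementation differs.

The train/test split draws 80% of each class independently
(`round(fraction × class size)`), so class proportions are conserved to
±1 compound, and is reproducible from its seed.

## Descriptor engine

Commercial descriptor software is replaced by an open set computed with
ChemmineR/ChemmineOB and the `obabel` CLI: 23 2D descriptors
(lipophilicity via logP and molar refractivity, H-bond counts, TPSA,
aromatic atom/bond counts, ring counts, element counts, rotatable
bonds, sp³ carbon fraction, and Gasteiger partial-charge statistics
including negative-charge counts) plus 6 optional 3D shape descriptors
(smallest principal moment of inertia, normalized inertia ratios
NPR1/NPR2, radius of gyration, span, asphericity) from a single
embedded conformer. The goal is *category fidelity* — lipophilicity,
aromaticity, partial charges, polar surface, shape are the descriptor
families that drive CYP2C9 inhibition models — not numeric
reproduction of any commercial descriptor. A `conformer_seed` argument
exists for interface stability, but the bundled embedding backend
(`obabel --gen3d`) is deterministic and ignores it.

Descriptor matrices then pass through three transforms, each recorded
in a provenance attribute so the processed matrix can be replayed
bit-for-bit from the raw one:

1. **Correlation pruning** (`prune_correlated`, cutoff |r| ≥ 0.85):
   columns are scanned left-to-right against the survivors; of a
   violating pair the lower-variance column is removed (tie: the
   alphabetically later name). The post-state — no surviving pair at or
   above the cutoff — is verified in the tests by an exhaustive
   pairwise-Pearson oracle, and the operation is idempotent.
2. **Near-zero-variance pruning**: constants are always removed; a
   non-constant column is removed when its most-frequent /
   second-most-frequent count ratio exceeds 19 *and* its distinct-value
   fraction is below 10% (the conventional two-part rule; "near null
   variance" has no standard closed definition, so both thresholds are
   configurable).
3. **Standardization** (`standardize`): per-column mean 0, sd 1
   (denominator n−1), fitted on the training set only; stored
   parameters are applied unchanged to test and screening data. Only
   the SVM consumes scaled inputs — the forest sees raw values, since
   tree splits are scale-invariant.

## Interaction energies

IE tables carry one kcal/mol score per molecule per conformation
(`id,1R9O,5XXI,MD1,...,MD5`). The docking-output parser accepts the
common `RESULT:`-line dialect and a generic `mode, score` table, and
always returns the best (most negative) mode, tolerating 1–10 modes.
The reference grid settings exposed by `default_job_spec()` — center
(8.208, 32.219, −1.923), 25 Å box, resolution 1 Å, exhaustiveness 8,
10 modes — are bookkeeping for reproducing docking runs externally;
no docking engine is executed by the package.

The screening filter demands IE **strictly below** the threshold for
*every* conformation; a score exactly at the threshold fails. The
default −8.5 kcal/mol corresponds to the 75% quantile of
training-inhibitor scores pooled over molecules and conformations;
`ie_threshold_from_inhibitors()` re-derives it from data. The original
description of that quantile is ambiguous between pooled, per-
conformation, and fraction-of-inhibitors-passing readings; the package
implements the pooled-quantile reading as the default and keeps the
single global threshold as the operative setting, since one number is
applied to all seven conformations. Incomplete profiles raise errors
rather than failing silently, so missing docking runs surface.

## Model training

* **mtry ceiling**: the number of descriptors sampled per split is
  bounded by ⌊√p⌋ (p = 177 gives 13).
* **RF grid**: ntree ∈ {25, 50, 100, 200, 300, 400, 500} (covering the
  25–500 range with roughly logarithmic spacing), mtry from 5 up to
  ⌊√p⌋. The winner is the highest mean CV accuracy; ties prefer the
  smaller ntree, then smaller mtry (cheapest adequate forest).
* **SVM grid**: cost over the ten powers of two 2⁻²…2⁷; the RBF width
  σ (kernlab parameterization) is not published, so the package uses
  the median heuristic — the inverse median pairwise squared distance,
  on up to 500 seeded sample rows — with multipliers {0.5, 1, 2}.
* **Cross-validation**: stratified 10-fold × 5 repeats; repeat r is
  seeded with seed + r, and the *same* folds are reused across all
  grid points of one scan so comparisons are paired.
* **Feature selection**: the mean decrease-in-Gini importance is
  averaged over many independently seeded forests (run r uses
  seed + r). The reference run count is 2000; because only the
  stability of the *mean ranking* matters, the test-suite and the
  acceptance script use 200 runs, which the convergence test shows is
  already stable for the benchmark. Selection is by rank (`top_k`) by
  default; an absolute threshold mode (`above_threshold`) exists, but
  absolute Gini values scale with the sample size, so ranks transfer
  across datasets and thresholds do not. All ranking ties break
  alphabetically for determinism.
* **Class scores** are auxiliary (the consensus needs only hard
  labels): the forest reports the fraction of tree votes; the SVM a
  logistic transform of its decision value, with the link fitted on
  the training decision values.

The random-forest backend is `ranger`, whose impurity importance is
the mean decrease in Gini; its speed is what makes the repeated-forest
importance procedure practical. One unit test cross-checks the
importance ranking against the independent `randomForest`
implementation.

## Evaluation

Confusion-matrix metrics use the standard closed forms, reported on
the percent scale (MCC × 100) to two decimals in written reports. A
zero MCC denominator returns 0, keeping reports total. Model
comparison uses the exact McNemar test on discordant correctness pairs
— the two models are evaluated on the *same* test set, so a paired
test is appropriate; the original work does not name its test, so this
choice is documented as an assumption and an unpaired two-proportion
z-test is available behind a flag for sensitivity analysis. The exact
two-sided p-value is 2·P(X ≤ min(b, c) | b + c, ½) capped at 1.

## Screening cascade

`screen_library()` composes the published cascade: consensus
(RF ∧ SVM) → IE filter (< threshold on all 7 conformations) →
stage-1 clustering of all prioritized hits (166-key structural keys,
cutoff 0.80) → stage-2 clustering of the stage-1 centroids only
(path-based fingerprint, cutoff 0.70) → candidate selection. Known
inhibitors can be removed up front via a user-supplied exclusion list;
no knowledge base is bundled. Selection takes the stage-2 centroid of
each cluster; clusters with more than 10 members earn
⌈size/15⌉ picks — a size rule that reproduces the published choices of
2 picks from an 18-member and 3 picks from a 37-member cluster — with
extra picks chosen by greedy max–min Tanimoto dissimilarity. Cascade
counts are asserted monotone non-increasing on every run.

## Synthetic benchmark

Real training data would require large assay downloads, so every stage
is exercised against seeded generators
(`fixture_spec()` / `gen_descriptor_table()` / `gen_ie_profiles()`)
that emulate the *statistical* structure the pipeline assumes:

* a two-class descriptor table with `n_informative` columns separated
  by `effect_size` standard deviations between classes
  (Normal(±effect/2, 1)) among `n_noise` standard-normal columns;
* matched IE profiles whose active class is shifted toward more
  negative energies, independently per conformation by default (a
  compound-symmetry correlation knob exists, default 0);
* an embedded table of 46 valid public-domain drug-like structures
  (plus two deliberately out-of-bounds molecules and one invalid
  SMILES for negative tests) for everything fingerprint-based.

Defaults are 300 actives + 300 inactives, 5 informative among 105
descriptors at effect size 1.5 — a deliberately hard ligand signal —
and IE means of −9.5 (actives) vs −7.0 (inactives) with sd 1.0, which
places the 75% quantile of active scores near the −8.5 kcal/mol
operating point and gives both classes realistic overlap at the
filter. The separable variant used for pipeline sanity checks raises
the effect size to 3, where a single informative column already
separates the classes at the Gaussian overlap bound Φ(1.5) ≈ 0.93.

What passing on these fixtures does **not** show: descriptor
redundancy structure of real chemistry (real descriptor blocks are
heavily correlated; the generator's columns are independent), docking
scores with pose-quality artifacts, activity-cliff behavior, or label
noise from inter-assay disagreement. The fixtures validate the
*machinery* — labeling, pruning, selection, tuning, the cascade's set
algebra — not chemical generalization.

### Problem sizes used in the shipped checks

The test-suite and acceptance script run, per seed: 200-run importance
at 600 × 105 (planted-descriptor recovery over 20 seeds), 10 × 5 CV
scans at 300 molecules (separability and label-permutation
controls), 100 seeded 50-candidate cascade trials against a
brute-force conjunction oracle, 50 random 200 × 40 pruning matrices
with injected duplicate/negated columns, and leader-clustering
comparisons against an independently computed similarity oracle on the
full embedded molecule set at cutoffs 0.70/0.80/0.85.

## Numerical choices and degenerate inputs

* Quantiles use R's default type-7 (linear interpolation).
* Pearson r is computed on complete rows; a zero-variance column's
  correlation is treated as 0 during pruning (it is removed by the
  variance rule instead).
* Tanimoto similarity of two empty fingerprints is defined as 0 off
  the diagonal and 1 on it.
* Standardization refuses constant columns (prune first); applying
  stored parameters never re-fits.
* All RNG flows through integer seeds; child seeds are derived as
  `seed + offset` modulo 2³¹.
* Fold assignment requires each class to have at least as many members
  as folds, otherwise a stratification error is raised.

## Known limitations

* Protonation at physiological pH is not modeled; molecules are used
  in neutral canonical form (a config hook accepts pre-protonated
  SMILES).
* The 3D block uses a single embedded conformer; conformer ensembles
  and quantum-derived charges are out of scope.
* Fingerprints are open substitutes (FP2, Open Babel MACCS) for the
  proprietary fingerprints used in the original workflow; cluster
  *counts* on real libraries will differ even though the algorithm and
  cutoffs match.
* Absolute Gini-importance thresholds do not transfer across sample
  sizes; prefer rank-based selection.
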