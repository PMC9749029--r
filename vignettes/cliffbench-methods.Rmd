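---
title: "Benchmarking bioactivity regression on activity cliffs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking bioactivity regression on activity cliffs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An *activity cliff* is a pair of structurally very similar molecules whose
measured potencies against the same target differ by an order of magnitude
or more. Cliffs concentrate the information medicinal chemists care most
about — the small structural edits with large potency consequences — and
they are precisely where regression models of bioactivity tend to fail,
because most learners implicitly assume a smooth structure-activity
landscape. cliffbench evaluates descriptor-based QSAR regressors *on their
cliffs*, not only on average, by carrying a cliff label through the entire
pipeline: curation, cliff detection, splitting, training, and a
cliff-restricted error metric.

## Pipeline and model

### Curation

Raw per-target tables (SMILES, activity in nM, replicate rows, optional
validity comment) pass through, in order:

1. **Validity filter** — rows with a non-empty validity flag are dropped.
2. **Sanitization** — SMILES are parsed and canonicalized with Open Babel;
   +1/−1 charged centres are neutralized (quaternary nitrogens and other
   permanent charges are kept); multi-fragment records (salts, mixtures)
   and unparseable strings are rejected.
3. **Replicate aggregation** — per canonical structure, Dixon's Q test
   (two-sided, α = 0.05, applied once to the more extreme of min/max, valid
   for 3–30 replicates) may remove one outlying annotation; the arithmetic
   mean in nM is then converted to p-units, p = −log10(nM·10⁻⁹). Molecules
   whose log10(nM) replicate standard deviation exceeds 1 log unit are
   removed: such dispersion usually signals inconsistent assays rather than
   measurement noise. Means are taken in nM *before* the log transform;
   the SD filter operates on the log scale, where "1 log unit" is defined.
4. **Stereo-duplicate removal** — groups of records with *different*
   canonical SMILES but *identical* ECFPs (the fingerprint is blind to
   stereochemistry) indicate inconsistently annotated stereoisomers whose
   activities cannot be attributed to a single structure; the whole group
   is removed, not just the later members, since there is no principled way
   to pick the "right" one.

Dixon's critical values are the published two-sided α = 0.05 table
(n = 3…30), embedded as constants and cross-checked at development time by
Monte-Carlo simulation of the Q statistic under normality. Outside 3–30
replicates the test is skipped (the SD filter still applies).

### Cliff detection

Structural similarity is a *soft consensus* of three measures, any one of
which qualifies a pair as similar at threshold 0.9:

* **substructure** — Tanimoto coefficient on hashed extended-connectivity
  fingerprints (radius 2, folded to 1024 bits);
* **scaffold** — Tanimoto on the ECFPs of the Bemis–Murcko frameworks
  (ring systems plus linkers, atom types retained; acyclic molecules have
  an empty framework, similar only to other empty frameworks);
* **SMILES string** — 1 − Levenshtein distance / max string length, on the
  canonical SMILES.

A similar pair is an activity cliff when its activities differ at least
ten-fold in nM, equivalently at least one p-unit. Both thresholds are
**inclusive** (≥ 0.9, ≥ 10): with inclusive bounds the nM-scale and
p-scale formulations coincide exactly, which the test suite asserts as the
identity `fold ≥ 10 ⟺ |Δp| ≥ 1`. Both bounds are configurable for users
who want strict inequalities. A molecule in at least one cliff pair is a
*cliff compound*; the per-molecule label drives stratification and the
cliff-restricted error.

### Splitting

Molecules are clustered on the ECFP Tanimoto affinity matrix with
normalized spectral clustering (five clusters by default; eigenvectors of
the symmetrically normalized affinity, row-normalized, k-means with a
fixed seed and 20 restarts). Within every cluster an 80/20 split is drawn
*stratified on the cliff label*, with largest-remainder rounding across
strata and a guarantee of one test molecule per cluster of size ≥ 2. The
affinity default is the Tanimoto similarity used directly as a precomputed
affinity; a Gaussian transform exp(−d²/2σ²) of the Tanimoto distance is
available as an option (`gaussian_affinity`, σ default 1.0) for users who
prefer a literal kernel — a precomputed affinity bypasses any kernel, so
only one of the two can be the default, and the direct similarity requires
no bandwidth choice.

An audit quantifies train/test representativeness: for every descriptor
family, the mean distance of each training molecule to its five nearest
training neighbours (self excluded) is compared with the mean distance of
each test molecule to its five nearest *training* neighbours, by a
two-sided Mann–Whitney U test, Benjamini–Hochberg corrected across
families at FDR 0.05. Jaccard distance serves the binary families, and
Euclidean distance (after standardization with training statistics) the
real-valued ones — the canonical metric for each type.

### Descriptors

* **ECFP** — 1024-bit, radius 2, hashed, via Open Babel.
* **MACCS** — the 166 predefined substructure keys.
* **PHYSCHEM** — 11 drug-likeness properties, in order: molecular weight,
  predicted logP, molar refractivity, topological polar surface area,
  formal charge, H-bond donors, H-bond acceptors, rotatable bonds, atom
  count (hydrogens included), ring count, heavy-atom count. The logP and
  molar refractivity are Open Babel's atom-contribution predictions; any
  fixed, documented atom-contribution scheme serves the purpose, since
  these columns are standardized before modelling.
* **WHIM** — 114 three-dimensional statistics of the conformer's weighted,
  centred atomic coordinates: for each of seven weighting schemes (unit,
  atomic mass, van der Waals volume, Sanderson electronegativity, atomic
  polarizability, first ionization energy, Kier–Hall intrinsic state, all
  relative to carbon) the three principal variances λ, their proportions,
  three axial symmetry scores (inverse Shannon information of the
  mirror-pair partition of the axis scores), and three inverse kurtoses;
  plus the global size, acentricity, density and volume combinations. The
  implementation reproduces the reference 3D-descriptor toolkit's values
  exactly on the table-free unit-weight components (frozen oracle values in
  the test suite); the per-element weight tables are standard published
  constants embedded in the source.

Conformers for WHIM come from seeded experimental-torsion knowledge
distance-geometry embedding with MMFF94 refinement, executed through a
batched RDKit subprocess — the one step delegated to Python, because a
reproducibility contract (same SMILES + seed ⇒ bit-identical descriptors)
requires a seedable embedder and Open Babel's 3D builder is time-seeded.
Molecules that fail to embed are dropped from WHIM-based experiments only,
with a warning, leaving the other descriptor families untouched.

Real-valued families (WHIM, PHYSCHEM) are standardized to zero mean and
unit variance **using training-set statistics only**; zero-variance
features map to zero on both sides. Binary families are used as-is.

### Models and tuning

Five regressors cover the classic descriptor-based repertoire, with the
benchmark's hyperparameter protocol — at most 50 configurations, fivefold
cross-validated mean RMSE, folds stratified on the cliff label, best
configuration refit on the full training set:

| algorithm | grid | backing implementation |
|---|---|---|
| KNN | k ∈ {3, 5, 11, 21} | in-package (Euclidean, neighbour-mean) |
| SVM (RBF) | γ ∈ {10⁻⁶…10⁻¹}, C ∈ {1, 10, 10², 10³, 10⁴} | e1071 |
| GBM | stages ∈ {100, 200, 400}, depth ∈ {5, 6, 7} | xgboost (learning rate 0.1) |
| RF | trees ∈ {100, 250, 500, 1000} | randomForest |
| MLP | lr ∈ {5·10⁻⁴, 5·10⁻⁵, 5·10⁻⁶}, width ∈ {256, 512, 1024}, depth 1–5 | in-package |

Every grid has at most 45 points, so within the 50-evaluation budget the
search is simply exhaustive; a Gaussian-process search would add a
stochastic dependency without evaluating fewer configurations. Ties go to
the earlier grid row. The MLP uses ReLU hidden layers of equal width, Adam,
mini-batches of 64, early stopping with patience 10 on an internal 10 %
validation split, and at most 500 epochs; batch size and the validation
fraction are design choices documented here, not protocol constants.

### Evaluation

For a test set with predictions ŷ and labels y,

* RMSE = √(Σᵢ (ŷᵢ − yᵢ)² / n) over all n test molecules, and
* RMSE_cliff, the same quantity over the n_c cliff compounds only
  (undefined — `NA`, never 0 — when n_c = 0).

R² or Q² are deliberately not computed: their denominators depend on the
response range of each split, which would bias comparisons across
datasets. The method-by-dataset matrix of either metric feeds a global PCA
ranking: two synthetic anchor rows holding the per-dataset column minima
("Best") and maxima ("Worst") are appended to stretch the projection,
columns are mean-centred but not rescaled (all cells share log-unit
scale; per-column standardization would erase between-dataset difficulty
differences the anchors express), anchors participate in the fit, and the
sign of the first component is fixed so "Best" sits left of "Worst".
Coordinates are also reported min-max scaled along the Best–Worst axis.
The failure-mode analysis reports, per dataset, the Pearson correlation
across methods between RMSE and RMSE_cliff and the mean excess cliff
error, and correlates both against training-set size.

## The synthetic-data generator

`generate_congeneric_dataset()` emulates the statistical structure of a
curated target dataset without any download: up to five congeneric
scaffold families built by enumerative decoration of template SMILES
(halogen / alkyl / ether substituents at two fixed positions), p-activities
drawn as a family baseline plus Gaussian noise (default SD 0.2 log units —
typical inter-assay reproducibility), planted cliff pairs with a 2-log gap
(comfortably beyond the 1-log criterion), and injected curation artifacts:
triplicate annotations, Dixon-detectable wild replicates, over-dispersed
replicate sets, validity-flagged rows, and enantiomeric SMILES pairs that
collide on achiral fingerprints. Substituents never touch the ring
systems, so scaffold similarity is exactly 1.0 within a family and the
planted pairs pass the similarity consensus by construction; the template
frameworks are heterogeneous enough that all cross-family similarities
stay far below 0.9 (the suite asserts the margins). The generator returns
the *exact* expected cliff set — every same-family pair whose final
activities differ at least ten-fold — rather than only the planted list,
because a planted 2-log gap leaves no room for a third family member to be
within one log of both ends, and induced pairs are therefore real cliffs.
Analogs whose folded ECFPs collide are skipped during enumeration, so
clean molecules are guaranteed to survive the stereo-duplicate filter.

What passing tests on these fixtures *do* show: the pipeline's filters
remove exactly what they should, the detector implements its definition,
the split preserves proportions, models behave sanely on learnable and
unlearnable responses. What they *cannot* show: behaviour under real
assay heterogeneity, activity distributions of real target families,
scaffold diversity beyond template decoration, or the empirical error
levels of models on public bioactivity data.

## Numerical choices and degenerate inputs

* Tanimoto of two all-zero fingerprints is 1.0 (a degenerate-identity
  convention); empty-vs-nonempty frameworks score 0.0, empty-vs-empty 1.0.
* Two empty strings have SMILES similarity 1.0; the Levenshtein
  denominator is the longer string length, the standard [0, 1] scaling.
* Largest-remainder rounding breaks ties deterministically (lowest
  stratum first); k-means uses 20 seeded restarts; eigen-decompositions
  are deterministic.
* Dixon's test is skipped for n < 3, n > 30, and zero-range replicate
  sets; aggregation of a single record has SD 0 by definition.
* Seeds: every stage derives its seed from the master seed and its stage
  labels via a 31-ary polynomial string hash modulo 2³¹ − 1, so streams
  are decoupled and any artifact can be reproduced from the manifest.
* Default test-suite problem sizes — families of 10–24 analogs, datasets
  of 40–100 molecules, response surfaces of n = 500 × 11 — were chosen to
  exercise every code path at interactive runtimes.

## Known limitations

* Open Babel's ECFP hashing differs bit-for-bit from other toolkits'; all
  similarity statements are internally consistent but absolute Tanimoto
  values are toolkit-relative (thresholded decisions at 0.9 proved robust
  on the fixtures either way).
* Open Babel is permissive about unusual valences, so REJECT_PARSE catches
  syntax errors but not every chemically dubious structure.
* The WHIM weight tables cover H, B, C, N, O, F, Si, P, S, Cl, Br, I;
  other elements fall back to carbon weights.
* The MLP is a plain-R implementation: correct and deterministic, but not
  fast enough for very large grids on large datasets; the default
  benchmark methods therefore favour the kernel and tree learners.
* Criterion-level reproduction of published per-target dataset statistics
  requires downloading the corresponding public bioactivity exports, which
  the package deliberately does not automate; `read_raw_csv()` accepts the
  released column vocabulary directly.
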