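---
title: "Consensus virtual screening: models, parameters and design choices"
author: "consensusVS maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus virtual screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
curation and labeling model, the seven molecular representations, the
classifier families and their probability scores, the consensus score and
screening funnel, the atom-level attribution formula, and — where the
protocol left genuine freedom — the design choices this package made and
why.

## The problem

Ligand-based virtual screening ranks a large commercial compound library
by the predicted probability that each molecule inhibits a target (here,
the protocol was developed around a serine/threonine kinase), so that a
handful of candidates can be purchased and assayed. The package
implements the full protocol as a reusable library: curate public
bioactivity records into a binary-labeled training set, train
fingerprint-based classifiers, average their probability scores into a
consensus, funnel a library through consensus, novelty, clustering and
PAINS filters, and explain the surviving predictions atom by atom.

## Curation and labeling

Raw activity records (compound id, SMILES, potency, potency type) are
standardized: the largest carbon-bearing fragment is kept (salt and
counter-ion removal), formal charges are neutralized where a neutral
protonation state exists (carboxylates, phenolates, ammonium and related
groups; quaternary nitrogens are left charged), and the structure is
canonicalized through OpenBabel. Deduplication keys on the InChI of the
standardized structure, which is robust to SMILES aliasing.

Replicate potencies for one structure are aggregated as follows: one
value passes through; two values are averaged; with three or more, every
value deviating by more than 25% from the mean of the full set is
removed in a single pass and the survivors are averaged. The single-pass
reading (deviations measured against the initial mean, on the µM scale,
not iterated) is the simplest consistent interpretation of the rule; an
iterative variant would need a stopping criterion the protocol never
states. A replicate set in which no value survives discards the
compound.

Labels are assigned from the aggregated potency in micromolar: potency
at or below 0.1 µM (pIC50 at least 7) is *active*, potency at or above
0.5 µM is *inactive*, and everything strictly between is excluded from
the dataset. The source material states the inactive boundary once as
"greater than 0.5 µM" and once as "≥ 0.5 µM"; this package adopts the
inclusive reading (0.5 µM itself is inactive), which matches the pIC50 ≤
6.3 gloss within rounding. Censored measurements (relation `>` or `<`)
carry no usable point estimate and are dropped with an audit reason; the
protocol is silent on them. Every dropped record lands in an audit log,
and input record counts always reconcile exactly with output-plus-audit
counts.

## Molecular representations

Seven representations are computed on an internal molecular graph parsed
via ChemmineR/OpenBabel (kekulized bonds, formal charges, implicit
hydrogens from default valences, ring perception with aromaticity
flags):

* **morgan** — circular fingerprint, radius 2, hashed to 2048 bits.
  Initial atom invariants encode element, heavy degree, hydrogen count,
  formal charge, ring membership and aromaticity; each iteration hashes
  the invariant with the sorted (bond code, neighbor invariant) pairs.
  Every bit records its generating atom environments (center, radius,
  atom set), which is what makes exact bit-to-atom retro-mapping
  possible later. Duplicate environments (identical bond sets) set no
  additional feature, mirroring standard circular-fingerprint
  deduplication.
* **rdkit / layered / pattern** — subgraph fingerprints over simple bond
  paths of one to seven bonds, hashed to 2048 bits under kind-specific
  typing: full atom typing for the subgraph kind, five typing layers
  (bond-only, element-only, element+bond, +aromaticity, +ring) for the
  layered kind, and generic ring/aromaticity typing for the
  substructure-screening kind.
* **pharm2d** — 2D-pharmacophore fingerprint over five feature families
  (H-bond acceptor, H-bond donor, positive ionizable, negative
  ionizable, aromatic), combinations of two and three features, and
  binned topological distances. The protocol names no bin edges; this
  package fixes three conventional bins (0–2, 3–5, 6–8 bonds) so the
  vector length is stable: 15 family pairs × 3 bins + 35 family triples
  × 10 distance-bin multisets = 395 bits.
* **pubchem** — an 881-bit substructure-key fingerprint following the
  public key layout: hierarchic element counts (115), ring census by
  size and composition (148), bonded element pairs (64), atom
  neighborhoods without (89) and with (44) bond orders, short linear
  fragments (253) and aromatic-substitution patterns (168). The exact
  published key table could not be transcribed faithfully, so the key
  definitions inside each section are this package's own deterministic
  enumeration; section spans, total length, determinism and substructure
  monotonicity match the published layout, but the vectors are not
  bit-compatible with other toolkits. This mirrors the original
  protocol's use of bespoke in-house scripts for this representation.
* **descriptors** — 128 physicochemical and topological descriptors
  (element and ring censuses, hydrogen-bonding counts, connectivity and
  shape indices, Wiener/Zagreb/Balaban indices, a polar-surface-area
  estimate from the common N/O environment contributions, coarse
  atom-contribution logP and molar refractivity, electrotopological
  state summaries, Moreau–Broto autocorrelations, Burden-matrix
  eigenvalues and distance-matrix statistics). The identity of "128
  descriptors" is inherently toolkit-dependent, so the list is pinned in
  a versioned manifest (`descriptorNames()`); non-finite values are
  imputed to zero with a warning.

Tanimoto similarity is |A∧B|/|A∨B| with the convention that two empty
fingerprints are identical (similarity 1) and an empty versus non-empty
pair is dissimilar (0); the same conventions define the Tanimoto kernel.

## Classifiers and probability scores

Four algorithm families are tuned over exactly the published grids: RF
(max_features ∈ {sqrt, log2, all} × n_estimators ∈ {100, 500}), SVM
(C ∈ {0.01, 0.1, 1, 10, 100} × kernel ∈ {linear, tanimoto}), KNN
(n_neighbors 1–30 × weight ∈ {uniform, distance}), MLP (three hidden
architectures (50,50,50), (50,100,50), (100) × solvers lbfgs/adam/sgd ×
activations identity/logistic/tanh/relu × learning rates 1e-2…1e-5).

Every model emits a probability score PS ∈ [0, 1] for the active class;
PS ≥ 0.5 is the predicted label. The PS definitions are: fraction of
trees voting active (RF), (distance-weighted) fraction of active
neighbors with the convention that exact matches dominate (KNN),
logistic output (MLP), and cross-validated sigmoid (Platt) calibration
of the decision values (SVM) — margin classifiers have no native
probability, and calibration on 3-fold cross-validated decision values
is the standard way to obtain one.

Implementation notes: Random Forest is delegated to `randomForest`, SVM
optimization to `kernlab` through precomputed kernel matrices (the
linear kernel as an inner-product matrix, the Tanimoto kernel from the
similarity above; the Tanimoto kernel is refused on non-binary input).
KNN and the MLP are implemented in the package: no installed R backend
offers a KNN with the required probability output, nor an MLP with
three hidden layers and the lbfgs/adam/sgd solver set. The MLP uses
binary cross-entropy with a small L2 penalty, Glorot-uniform seeded
initialization, an epoch cap of 200 with early stopping (five
consecutive loss improvements below 1e-4), and drops constant input
columns before fitting (they carry no information, and fingerprint
matrices are mostly constant-zero columns). Non-convergence is logged,
not fatal. Descriptor inputs for the scale-sensitive learners (SVM,
KNN, MLP) are z-scored with statistics fit on the training portion
only; fingerprints are used raw, and the KNN metric on raw bit vectors
(Euclidean, equivalent in ordering to Hamming) is the documented
default.

Model selection is 5-fold cross-validated accuracy over the full grid,
with ties broken by deterministic grid-enumeration order; the fold
assignment is made invariant to dataset row order by canonicalizing rows
through a content hash first. Validation is 10 repeats of stratified
70/30 Monte-Carlo splitting — the protocol's own wording ("trained 10
times with a random sample corresponding to 70%") describes repeated
subsampling, not standard 10-fold partitioning. The y-randomization
control permutes training labels per repeat, refits with the selected
hyperparameters and evaluates by the same held-out protocol; a genuine
structure–activity signal collapses to accuracy ≈ 0.5 under
permutation.

## Consensus scoring and the screening funnel

The consensus score CS of a compound is the arithmetic mean of the
member PSs; CS ≥ 0.5 predicts active. All subsets of size ≥ 2 of a model
set are enumerable (2^n − n − 1 combinations; 11 for four models) and
ranked by accuracy with precision as tiebreak, which reflects the
protocol's emphasis on precision for screening use. A threshold sweep
(defaults 0.5–0.9) reports precision, recall and predicted-active counts
per CS cutoff; counts and recall are non-increasing by construction.

The screening funnel applies, in order: standardization identical to
curation; consensus prediction with a CS ≥ 0.8 retention cutoff
(inclusive); a novelty filter removing hits whose maximum Tanimoto
similarity (circular fingerprint — the members' own representation; the
protocol does not name the fingerprint for this step) to any training
compound is ≥ 0.40; sphere-exclusion (Butina-style) clustering on the
subgraph fingerprint at similarity 0.70, visiting compounds in
decreasing neighbor-count order, with the highest-CS member of each
cluster flagged representative (ties to the lexicographically smallest
id); and annotation against a curated subset of the published
pan-assay-interference (PAINS) substructure families — roughly two dozen
SMARTS covering the quinone, catechol, azo, rhodanine/ene-one,
alkylidene-barbiturate, phenolic Mannich/hydrazone, and reactive-
electrophile archetypes. The full public catalog runs to several hundred
patterns; the subset is documented as such and alerts annotate rather
than silently delete (alerted compounds are excluded from the final
selection but kept in the annotated table). Stage counts are logged and
reconcile exactly; each stage's output is a subset of its input, so
raising any cutoff can only shrink the hit list.

## Atom-level attribution

Shapley values over fingerprint bits are estimated by the permutation
method: for each background compound, the bits on which the explained
compound and the background differ are flipped one at a time along a
random permutation and its reverse (antithetic sampling), accumulating
prediction deltas; bits on which both agree contribute exactly zero and
are skipped. Per background row the deltas telescope to f(x) − f(b), so
additivity — base value plus the sum of all bit scores equals the PS of
the explained compound — holds to machine precision by construction, not
approximately. Ten permutations per background row is the documented,
configurable default; the background is 100 training compounds sampled
stratified by label under a fixed seed when not supplied explicitly.
All members of a consensus are explained with the same seed, which makes
consensus averaging exactly idempotent for identical members.

Bit scores are retro-mapped to atoms through the recorded circular
environments: a bit with score fc, n_occ generating environments and
n_Atoms atoms per environment passes fc/(n_Atoms · n_occ) to each atom
of each environment — so per model the atom weights sum exactly to the
summed scores of the mapped on-bits (conservation, asserted to 1e-9 in
the tests). An environment's atoms are the center atom plus every atom
touched by a bond within the radius (the inclusive reading of "atoms in
the feature"). Scores on off-bits (features the molecule lacks but a
background compound has) have no atom image and are excluded from the
conservation sum with a warning. The final atom weight averages the
per-model weights across consensus members, and depictions shade atoms
warm for positive (activity-driving) and blue for negative weights.

## The synthetic data generator

The generator stands in for the external bioactivity database and
vendor libraries so the whole pipeline is testable offline. Actives are
benzofuran-2-carboxamides — the planted substructure, chosen to echo the
benzofuran chemotype the original study recovered — decorated from a
fixed vocabulary of halogens, small alkyl/alkoxy and amine substituents;
inactives come from fourteen scaffold-free decoy templates (pyridine and
benzene amides, sulfonamides, piperidines, benzothiazoles and similar
drug-like motifs). Distinctness is enforced on standardized structure
keys, so curation recovers the generated counts exactly. Potencies are
log-normal on either side of the excluded band (active median 0.02 µM,
σ₁₀ = 0.4, truncated at 0.1 µM; inactive median 5 µM, σ₁₀ = 0.5,
truncated at 0.5 µM) — medians sit an order of magnitude inside their
class regions, as in a typical curated kinase series. Twenty percent of
compounds receive three replicate measurements: two bracketing the
target potency tightly enough to survive the 25% rule and one injected
outlier (1.9× the target) that the rule must remove, so aggregation is
exercised with a known right answer. Screening libraries mix
scaffold-free decoys with heavily decorated scaffold analogs whose
decorations are deep enough that their circular-fingerprint similarity
to every training compound stays below the 0.40 novelty cutoff — this
was verified empirically and the decoration vocabulary frozen.

What the generator does *not* emulate: real structure–activity
landscapes (activity cliffs, multiple chemotypes per target), assay
noise correlated with potency, censored measurements at assay limits,
and the scale of real vendor libraries. Tests passing on these fixtures
demonstrate that the machinery is correct and that the protocol recovers
a planted signal; they do not certify predictive performance on real
kinase data, which depends on the data themselves.

## Problem sizes and numerical choices

The packaged tests run the study protocol at n = 400 (200 active / 200
inactive), the size at which the validation and randomization analyses
are performed, with smaller n = 120 fixtures for unit-level checks;
these sizes give stable statistics (held-out accuracy standard errors
of a few percent) while keeping the whole suite quick to run.
Tolerances: additivity of the explainer is asserted at 1e-6 (it holds
to ~1e-15), atom-weight conservation at 1e-9, the y-randomization mean
at ±0.05 around 0.5. Degenerate inputs are defined rather than left to
chance: empty-denominator metrics yield 0 with a warning, both-empty
fingerprints are identical, a zero-distance KNN query is decided by its
exact matches, single-class datasets are rejected at training, and grid
ties resolve to the first point in enumeration order.

## Known limitations

The fingerprints are this package's own hash implementations:
deterministic and structurally faithful, but not bit-compatible with
other toolkits, so absolute model metrics on real data will differ from
runs using other featurizers even under the same protocol. The PAINS
catalog is a curated subset. Charge neutralization is rule-based on
common charged groups rather than a full protonation model. Aromaticity
comes from ring perception rather than a full electron-counting model,
which can differ from other toolkits on exotic heterocycles. The MLP is
a compact implementation sufficient for the grid above; it is not a
general deep-learning backend.
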