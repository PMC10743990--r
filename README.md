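# consensusVS

Consensus machine-learning virtual screening for kinase-inhibitor
discovery, as an R package.

## The problem

Ligand-based virtual screening ranks a commercial compound library by
the predicted probability that each molecule inhibits a target, so a
small number of candidates can be purchased and assayed. `consensusVS`
implements a complete, reproducible protocol for this:

1. **Curation** — raw bioactivity tables (id, SMILES, IC50/Ki) are
   standardized (salt stripping, charge neutralization, canonical
   SMILES, InChI-keyed deduplication), replicate potencies aggregated
   with a 25% outlier rule, and compounds labeled *active* (potency ≤
   0.1 µM, i.e. pIC50 ≥ 7) or *inactive* (≥ 0.5 µM); the band in between
   is excluded. Every dropped record is auditable.
2. **Representations** — seven molecular encodings: circular
   fingerprints (radius 2, 2048 bits, with bit→atom provenance),
   three subgraph/path fingerprints (2048 bits), a 2D-pharmacophore
   fingerprint (395 bits), an 881-key substructure fingerprint and 128
   physicochemical/topological descriptors.
3. **Models** — RF, SVM (linear and Tanimoto kernels, |A∧B|/|A∨B|,
   with Platt-calibrated probabilities), KNN and MLP, tuned by 5-fold
   grid-search CV over the published hyperparameter grids and validated
   by 10 × stratified 70/30 splits plus a y-randomization control.
4. **Consensus** — each model emits a probability score PS ∈ [0,1]; the
   consensus score is the mean, CS = (1/m) Σ PSᵢ, with CS ≥ 0.5 ⇒
   active. All 2ⁿ − n − 1 member combinations can be enumerated and
   ranked, and precision/recall swept over CS thresholds.
5. **Screening funnel** — CS ≥ 0.8 retention, a Tanimoto < 0.40 novelty
   filter against the training set, Butina sphere-exclusion clustering
   at similarity 0.70 with highest-CS representatives, and PAINS
   substructure alerts.
6. **Attribution** — permutation Shapley values over fingerprint bits
   (exactly additive: base + Σ fc = PS), retro-mapped to atoms by
   fw_a = Σ_features fc / (n_Atoms · n_occ) and averaged over consensus
   members, with 2D depictions shading activity-driving atoms.

A synthetic-fixtures module generates activity tables and screening
libraries with a planted structure–activity signal (benzofuran
carboxamide actives vs. scaffold-free decoys), so the entire pipeline is
testable without any external download.

## Worked example

```r
library(consensusVS)

# synthetic study data: 60 actives + 60 inactives, replicates included
cfg <- syntheticConfig(n_actives = 60, n_inactives = 60, seed = 7)
ds  <- generateDataset(cfg)
cur <- buildDataset(ds$records, "train")
cur
#> LabeledDataset (train): 120 compounds (60 active / 60 inactive)
#>   potency range: 0.002317 - 89.82 uM; 0 records dropped in audit

fm <- featurizeDataset(cur, "morgan")
X <- featureData(fm); y <- activityLabels(cur)

knn <- trainClassifier("KNN", X, y, list(n_neighbors = 5L, weight = "uniform"))
rf  <- trainClassifier("RF",  X, y, list(max_features = "sqrt",
                                         n_estimators = 100L))
cons <- consensusModel(knn, rf)

# screen a 80-compound library (25% hidden scaffold analogs)
lib <- generateScreeningLibrary(cfg, n_library = 80, hit_fraction = 0.25)
res <- runFunnel(cons, standardizeLibrary(lib$smiles), cur)
res$funnel
#>  library  cs_pass    novel clusters selected
#>       80       17        5        2        2
```

Reading the funnel: of 80 library compounds, 17 score CS ≥ 0.8; 5 of
those are structurally novel (maximum Tanimoto similarity to every
training compound below 0.40); they fall into 2 clusters, whose 2
highest-CS representatives carry no PAINS alert and become the final
selection. On this fixture all retained hits are true planted-scaffold
analogs.

Validation against chance:

```r
yr <- yRandomization("KNN", X, y, list(n_neighbors = 5L, weight = "uniform"),
                     n_repeats = 5, n_splits = 5, seed = 11)
round(mean(yr), 3)
#> [1] 0.521   # permuted labels: accuracy collapses to ~0.5
```

Atom-level explanation of one predicted active:

```r
ex <- explainCompound(cons, ds$truth$smiles[1], X[seq(1, 120, 6), ],
                      n_permutations = 5, seed = 2)
head(ex$table)                     # atom, element, mean weight
renderAtomWeights(ds$truth$smiles[1], ex$weights, "weights.png")
```

A thin command-line wrapper ships in `inst/scripts/consensusvs.R`
(subcommands `synth`, `curate`, `run`, `version`), and
`inst/scripts/chembl_replication.R` contains the optional full-scale
replication experiment for users with locally exported bioactivity
tables.

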