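# editcode

Structure-aware modeling of adenosine-to-inosine (A-to-I) RNA editing from
saturation-mutagenesis variant libraries.

ADAR enzymes edit specific adenosines in double-stranded RNA, and the
efficiency of each site is governed by the surrounding sequence and
secondary structure. `editcode` is for researchers dissecting this
*cis*-regulatory code with mutagenesis experiments: given a hairpin
substrate, a library of designed variants, and per-variant editing levels
(measured from reads or simulated), it builds structure-aware features and
trains interpretable gradient-boosted-tree models of editing.

## What it computes

- **Editing quantification and standardization.** Editing level
  `EL = G/(A+G)` at the site among reads exact-matched to each variant;
  per-library Z-scores `Z_i = (EL_i − EL_WT)/S` with
  `S = sqrt(mean((x_i − x̄)²))`, `x_i = EL_i − EL_WT` (the WT variant scores
  exactly 0).
- **Folding.** A built-in, enumeration-verifiable DP engine (simplified
  per-pair energies GC/AU/GU = −3/−2/−1 kcal/mol): MFE structure and
  energy, partition function `Z`, ensemble free energy `G = −kT ln Z`, MFE
  frequency `exp(−(E_MFE − G)/kT)`, ensemble diversity
  `2 Σ p_ij(1 − p_ij)`, and base-pair probabilities — all under optional
  hard constraints (`. x | < >`). A backend adapter swaps in `RNAfold`
  when available.
- **Probability of the active conformation.**
  `P = exp(−E_wt/kT)/Z / max(1, n_noncanon)` with `kT = 0.6` kcal/mol
  (37 °C): the Boltzmann weight of the constrained WT-like core over the
  unconstrained ensemble, penalized by reference-core pairs the variant can
  no longer form canonically.
- **Structural annotation and similarity.** bpRNA-style elements (stems,
  hairpins, bulges, internal loops, multiloops, exterior) with closing
  pairs; editing-site context (site element, u1–u2, d1–d3, −1/+1 and
  opposing nucleotides); tree-edit structure similarity in [0, 1]
  (1 = identical).
- **Mutation taxonomy.** Six classes per single substitution:
  transition/transversion × {none, +break, +shift}.
- **Modeling.** Per-mutated-base feature matrix (~130 named features in
  nine groups), leakage-free 70/15/15 position splits with co-mutation
  grouping, gradient-boosted trees (≤1000 rounds, early stopping after 10
  rounds without validation-RMSE improvement), regression/classification
  metrics, and TreeSHAP feature/group attribution.
- **Synthetic data.** A generator that emulates the whole experiment
  (substrate, library, planted logistic editing function, binomial reads),
  so every stage is testable without downloads.

## Worked example

```r
library(editcode)

spec <- synth_spec(seed = 7, n_singles = 30, n_doubles = 10, n_indels = 2)
sub  <- gen_substrate(spec)
sub
#> Substrate synth_seed7 ( 53 nt, editing site 19 )
#>   AAAAGCUGCGGCAUCAGCACGCGACAACAUCGCGCGCUGAAACCGCAGCCAAA
#>   ....(((((((..(((((.(((((.....))))).)))))..))))))).....

lib <- plant_editing(gen_library(sub, spec), sub, spec)
head(lib[, c("id", "mutations", "mean_editing", "zscore")], 4)
#>       id mutations mean_editing     zscore
#> 1     WT              0.6607867  0.0000000
#> 2 var001    33:C>U    0.1279920 -3.3059124
#> 3 var002    18:C>A    0.1007983 -3.4746453
#> 4 var003    28:C>A    0.5707264 -0.5588107
```

The WT is edited at its target level (0.66) and scores Z = 0; mutations in
the core stems (e.g. `18:C>A`, breaking a pair next to the editing site)
abolish editing. Running the full pipeline:

```r
res <- run_pipeline(list(synthetic = TRUE, seed = 7,
                         synth = list(n_singles = 30, n_doubles = 10,
                                      n_indels = 2)),
                    out_dir = "run1")
res$metrics
#> metrics on test split (5 variants):
#>   R2 = 0.922  Spearman = 0.900  Pearson = 0.977
#>   MAE = 0.0337  MAPE = 0.150  RMSE = 0.0458
#>   auPR = NA  auROC = NA
res$shap
#> SHAP report on test split; baseline = 0.2769
#> top features (percent contribution):
#>   sim_nor_score                 79.62%  [structure]
#>   probability_active_conf        6.22%  [structure]
#>   ensemble_diversity             4.48%  [structure]
#>   site_elem:internal             2.47%  [site_structure]
#>   mut_ref:C                      1.67%  [mutation_sequence]
```

The model explains 92% of test-split variance on this small simulated
library, and attribution recovers the planted drivers: structure
similarity to WT and the active-conformation probability dominate. (auPR
and auROC are NA here because all five test variants fall in the "edited"
class.) The output directory contains the library TSV, feature matrix CSV,
metrics JSON, SHAP importances, a Newick dendrogram of
structure-similarity clusters, and a run manifest sufficient to reproduce
the run bit-identically.

A command-line wrapper covers the same stages
(`inst/cli/editcode {simulate, design, quantify, fold, annotate,
featurize, train, explain, crosseval, cluster, run}`).

## Package layout

- `R/fold.R`, `src/fold.cpp` — energy model, MFE/partition DP, constraints,
  active-conformation probability, enumeration oracle, backend adapter
- `R/annotate.R` — dot-bracket parsing, element annotation, site context,
  structure trees, Zhang–Shasha similarity
- `R/variants.R` — substrates, mutation descriptors, designed-variant
  enumeration, read assignment, Z-scores, mutation taxonomy, TSV I/O
- `R/featurize.R` — versioned feature registry and matrix builder
- `R/model.R`, `src/gbm.cpp` — position splits, gradient-boosted trees,
  metrics, TreeSHAP
- `R/synth.R` — synthetic substrates, libraries, planted editing, reads
- `R/pipeline.R`, `R/cli.R` — orchestration, clustering, manifests, CLI
- `vignettes/editcode-methods.Rmd` — the model, its assumptions, and every
  numerical design decision
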