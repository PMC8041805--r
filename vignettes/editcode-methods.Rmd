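---
title: "Modeling cis-regulation of A-to-I editing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cis-regulation of A-to-I editing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editcode)
```

## The problem

ADAR enzymes deaminate adenosine to inosine (read as G by sequencers) in
double-stranded RNA. How strongly a given adenosine is edited depends on the
sequence and the secondary structure around it — the *cis*-regulatory code.
`editcode` models this code from saturation-mutagenesis experiments: a
hairpin substrate carrying one editing site is mutagenized (all single
substitutions, designed doubles, small indels), per-variant editing levels
are measured by amplicon sequencing, and gradient-boosted trees relate
structure-aware features of each variant to its editing level.

The package implements the full desk-side pipeline: a folding engine,
structural-element annotation, editing quantification and standardization,
featurization, leakage-free model training with Shapley attribution, a
synthetic-data generator, and a CLI orchestrator.

## Quantifying and standardizing editing

The editing level of a variant is $EL = G/(A+G)$ at the editing site among
reads assigned to that variant. Reads are assigned by exact signature
matching: a read belongs to a variant iff, with the editing-site position
masked, it equals the variant's sequence exactly. This is the desk-scale
substitute for the mapper used with real amplicon data; it assumes designed
variants are unambiguous outside the editing site (checked at index build)
and does no error correction. The minimum-read threshold defaults to 100
reads per variant (a conventional choice; configurable).

Editing levels are standardized per library as
$$Z_i = \frac{EL_i - EL_{WT}}{S}, \qquad
  S = \sqrt{\tfrac{1}{N}\sum_i (x_i - \bar x)^2}, \quad
  x_i = EL_i - EL_{WT},$$
with $\bar x$ the mean of the deviations $x_i$ (so $S$ is the *population*
standard deviation of editing levels, the population rather
than the sample convention). The WT variant scores exactly 0 by
construction.

## The folding engine

The built-in engine uses a deliberately simplified thermodynamic model:
independent per-pair energies (GC $-3.0$, AU $-2.0$, GU $-1.0$ kcal/mol), no
stacking or loop terms, a minimum hairpin of 3 unpaired nt, lone pairs
allowed. The point of this choice is verifiability: every quantity the
pipeline consumes — MFE structure, partition function $Z$, pair
probabilities $p_{ij}$ — can be checked against exhaustive enumeration
(`brute_force_fold()`), and the test suite does exactly that on hundreds of
random sequences. The `external_fold_adapter()` seam lets a Turner-model
folder (`RNAfold`) be substituted without touching downstream stages; when
the backend is missing the adapter raises a capability error rather than
silently falling back.

Ensemble quantities follow the standard conventions: ensemble free energy
$G = -kT\ln Z$; MFE frequency $\exp(-(E_{MFE}-G)/kT)$; ensemble diversity
$2\sum_{i<j} p_{ij}(1-p_{ij})$, the expected symmetric-difference distance
between two structures drawn independently from the ensemble. The partition
function is computed with per-nucleotide rescaling keyed to the MFE energy
density, so results stay finite to at least $n = 500$.

MFE ties are broken deterministically: the leftmost differing position is
preferred paired, and paired to its 5'-most admissible partner. This makes
pipeline outputs bit-reproducible.

### Hard constraints and the active-conformation probability

Constraint strings use one symbol per nucleotide: `.` free, `x` unpaired,
`|` paired, `<` paired downstream, `>` paired with an upstream partner. The
probability that a variant still folds into the WT-like ("active")
conformation is
$$P_{\text{active}} =
  \frac{e^{-E_{wt}/kT}}{Z} \Big/ \max(1, n_{\text{noncanon}}),$$
with $kT = 0.6$ kcal/mol (37 °C), $E_{wt}$ the energy of the minimum-energy
structure satisfying the substrate's constraint string, $Z$ the
*unconstrained* partition function, and $n_{\text{noncanon}}$ the number of
reference-core pairs that the variant can no longer form as canonical
(Watson–Crick or GU) pairs. Two numerical choices are pinned here: the
divisor is 1 when the noncanonical count is 0 (the division is otherwise
undefined), and a variant for which the constraint is unsatisfiable gets a
flagged missing value — featurization propagates it as missing, never as
zero. Indel variants change sequence length, so the substrate-level
constraint cannot apply to them; they are likewise flagged missing. This
mirrors the empirical situation in which the active conformation is only
computable for a majority subset of real variants.

## Structural annotation and similarity

Dot-bracket structures are segmented into typed elements — stems (maximal
stacked runs), hairpin loops, bulges (one-sided), internal loops
(two-sided), multiloops, and a single exterior element — such that every
nucleotide belongs to exactly one element; closing-pair identities are
recorded for loop-type elements. Coordinates are 1-based closed intervals.
For asymmetric internal loops, dims are reported 5':3' (which strand comes
first is a genuine convention choice; this order is fixed and documented).

The editing-site context walks the element sequence (ordered by first
position) to collect the site element, up to two upstream (`u1`, `u2`) and
three downstream (`d1`–`d3`) elements, the −1/+1 nucleotides, and the
opposing base (the Watson–Crick partner in a stem; the
antiparallel-aligned base of the other strand in an internal loop, so an
A:C 1:1 mismatch reports C).

Structure similarity converts each structure to an ordered rooted tree of
elements (labelled kind plus dims) and computes
$$\text{sim}(a, b) = \max\!\Big(0,\; 1 - \frac{d_{ZS}(a,b)}
  {\max(|a|, |b|)}\Big)$$
with Zhang–Shasha tree-edit distance under unit-cost
relabel/insert/delete. Published tree-comparison tools for this purpose do not document their
internal edit costs; this normalization
preserves the semantics that matter downstream — 1 means identical, the
score is symmetric, in $[0,1]$, and monotone in structural divergence. The
test suite checks the implementation against an independent exponential
forest-edit recursion on small trees.

## Featurization

One feature row is built per mutated base (a double mutant contributes two
rows; the WT contributes one row with `num_mutations = 0`). The registry
(version 1, ~130 features) spans nine groups: global structure
thermodynamics (`mfe`, `ensemble_energy`, `mfe_frequency`,
`ensemble_diversity`, `all_stem_length`, `probability_active_conf`,
`sim_nor_score`); mutation count; mutation sequence features (`mut_pos`,
`dist_to_site`, ref/alt one-hots); mutation structure features (element
kind at and around the mutated base, same-element-as-site flag); other
mutation features (SNP/indel, WT/mutated); editing-site sequence features
(`site_prev_nt`, `site_next_nt`, opposing base, integer-coded A=1..U=4);
editing-site structure features (element one-hots, loop dims, the
`site_1_1:A:C` mismatch flag, closing-pair one-hots such as
`site_5prm_cp_internal:C:G`); and upstream/downstream context blocks
(`u1`/`u2`, `d1`–`d3`, e.g. `d2_5prm_cp_internal:G:C`).

Feature sets of this kind are described in the literature as a scheme
rather than an exhaustive list (with inconsistent totals around 122-125);
the registry therefore implements every named or describable feature under
its documented name and is explicitly versioned. Features
that are entirely missing or non-varying on the **training** split are
masked from all splits. WT rows are included in training (a documented design choice). The binarized label defaults to
$EL > 0.01$ ("edited"), configurable.

## Model training and attribution

Positions (not variants) are split 70/15/15 into train/validation/test;
positions co-mutated in any variant are merged (union-find) and assigned
atomically, so no feature row of a test position ever informs training.
The no-leakage property is asserted programmatically on every pipeline run.
The WT row (position 0) goes to training by convention.

The learner is gradient-boosted regression trees in the XGBoost
formulation: squared-error (or logistic) objective, exact greedy splits
with gain $\frac{1}{2}(G_L^2/(H_L+\lambda) + G_R^2/(H_R+\lambda) -
G^2/(H+\lambda))$, leaf weights $-G/(H+\lambda)$, missing values routed
along learned default directions. The "default parameters" are pinned
(library defaults drift): $\eta = 0.3$, max depth 6, $\lambda = 1$,
min-child-weight 1, at most 1000 rounds with early stopping after 10
rounds without validation-RMSE improvement. Training is deterministic
(exact splits, no subsampling); the seed is recorded in the run manifest.
Variant-level predictions are the mean of a variant's per-base rows (a
documented design choice).

Attribution uses the path-dependent TreeSHAP recursion, whose additivity
(baseline + attributions = prediction, to 1e-6) is asserted in the tests.
Per-feature percent contributions are normalized to 100, summed per
registry group, and averaged across substrates for cross-substrate
rankings. auPR treats "edited" as the positive class; MAPE guards its
denominator with $\epsilon = 10^{-3}$.

## The synthetic-data generator

The generator emulates what the pipeline assumes about real experiments: a
hairpin substrate with stacked stems and small internal loops, the edited A
in a 1:1 A:C mismatch (the configuration of highly edited natural sites);
a designed library of all singles (minus A>G at ±1 of the site, which is
indistinguishable from editing), double transversions, compensatory stem
swaps, and ≤3-nt indels; planted editing levels
$\text{logistic}(b + w_1 P_{\text{active}} + w_2\,\text{sim} - w_3
n_{\text{mut}} + w_4\,\text{AC})$ with the intercept calibrated so WT sits
at 0.66 (a highly edited natural substrate's level); six replicates with
Gaussian noise (sd 0.02); and binomial reads at coverage 2000. Default
weights (2.5, 2.0, 0.4, 0.8) were chosen once so that single mutations
mostly cause moderate decreases while core disruptions abolish editing,
matching the qualitative shape of real libraries.

Two deliberate departures from naive emulation, both forced by the
leakage-grouping rule: doubles are designed over a disjoint position
matching (plus compensatory stem pairs) rather than uniformly at random,
because random pairs transitively merge nearly all positions into one
co-mutation group and empty the validation split; and variants with an
unsatisfiable constrained fold contribute $P_{\text{active}} = 0$ to the
*planted truth* while their feature value stays missing — the generator's
world knows the core is unformable even when the feature pipeline cannot
compute it.

What a green test does **not** establish: the generator has no PCR or
coverage biases, no sequencing-error structure beyond uniform
substitutions, no replicate batch effects, and its planted function is far
simpler than real ADAR regulation. Green acceptance means the pipeline
recovers what it assumes, not that the simplified energy model matches wet
thermodynamics.

## Interpreting the acceptance criteria

Position-based 15% test splits on a ~60-nt substrate hold few variants
(roughly 13–45), so the test-set $R^2$ of a single seeded run is
high-variance — the corresponding real-data figure spans 0.68–0.86 across
substrates. The end-to-end criterion is therefore evaluated across ten
seeded split/train runs: the three planted drivers must rank in the top-5
mean-|SHAP| features in at least 9 of 10 runs, and the *median* test $R^2$
must reach 0.8. The cross-family check trains on one synthetic substrate
family and evaluates on a second with different planted weights, requiring
an $R^2$ drop of at least 0.3 (with an identical-rule control family
confirming the drop is due to the changed regulatory rule, not the changed
substrate).

## Known limitations

- The simplified energy model has no stacking, loop, or dangling-end
  terms; absolute energies and probabilities are not comparable to
  Turner-model folders (use the `vienna` backend for that).
- No pseudoknots; no RNA–RNA hybrid folding; no suboptimal-structure
  sampling.
- Read assignment is exact-match only; indel-tolerant assignment and
  alignment are out of scope.
- `allow_lone_pairs = FALSE` is not supported by the builtin DP engine
  (only by enumeration and external backends); the default (allowed)
  matches the analyses this package models.
- Cross-substrate transfer is evaluated, but nothing in the model
  addresses it: feature distributions shift across substrates and the
  trees do not extrapolate — reproducing, by design, the empirical
  failure of cross-substrate prediction.
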