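---
title: "The hybrid graph-attention / descriptor IC50 model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hybrid graph-attention / descriptor IC50 model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The modelling problem

`ic50net` regresses the potency of small molecules — log10 of the
half-maximal inhibitory concentration, IC50, in nanomolar — from structure
alone. Note the response is log(IC50), not pIC50: there is no sign flip, so
*lower* predictions mean *more potent* compounds. Data of this shape come
from ChEMBL-style activity exports: one row per measured compound-target
pair, with a SMILES string, a target identifier, a reported concentration
and its unit.

Two families of representations dominate this problem. Fixed descriptor and
fingerprint vectors are interpretable and capture global physicochemistry
(lipophilicity, polarity, flexibility) but blur substructural detail.
Message-passing networks on the molecular graph learn local structure but
do not explicitly encode the global properties medicinal chemists reason
with. The model here runs both in parallel and fuses them.

## Model

**Graph branch.** Atoms are nodes, bonds are directed edge pairs. The node
*identity* is the element-hybridization tuple: Csp3 and Csp2 are different
entries of an 85-entry vocabulary (12 heavy-atom elements x 7 hybridization
labels + one out-of-vocabulary bucket), looked up in a learned 32-dimensional
embedding table. That embedding is concatenated with 10 numeric per-atom
features (atomic number, degree, formal charge, total hydrogen count,
aromatic and ring flags, R/S chirality flags, smallest-ring size, total
valence), projected linearly to width 128, and passed through two
multi-head graph-attention layers (2 heads of width 64, concatenated back
to 128; each layer followed by ReLU, batch normalization over nodes, and
dropout 0.2). Attention logits are computed from projections of the source
state, the target state *and* the 5 bond features (bond-type code,
conjugation, ring, aromaticity, stereo code), so edge chemistry conditions
the message weights; a plain attention layer would ignore bond attributes
entirely. Self-loops with all-zero edge features are added so every atom
attends at least to itself and softmax groups are never empty. The readout
concatenates global mean and global max pooling: a 256-dimensional graph
embedding.

**Descriptor branch.** Each molecule also becomes a 544-vector: a 512-bit
Morgan (circular) fingerprint of radius 2 followed by 32 physicochemical
descriptors. The vector is z-scored per dimension with statistics fitted on
the *training* set only, then encoded 544 -> 256 -> 128 (ReLU, batch
normalization, dropout 0.3 per layer).

**Fusion.** The 256-dimensional graph embedding, the 128-dimensional
descriptor embedding and one raw molecular-size feature (sum of heavy-atom
atomic numbers) concatenate to a 385-vector, which a single hidden layer of
64 units (ReLU, batch norm, dropout 0.2) maps to the scalar log10 IC50.

```{r}
library(ic50net)
fit <- ic50net(train_samples, test = test_samples)
print(fit)
predict(fit, c("CCO", "Clc1ccccc1"))
```

## The descriptor registry

The 32-descriptor registry contains molecular weight, LogP, TPSA, hydrogen
bond donor/acceptor counts, rotatable bonds, aromatic/aliphatic/saturated/
total ring counts, fraction of sp3 carbons, heavy atoms, assigned
stereocenters, formal charge, heteroatoms, valence electrons, molar
refractivity, the three Kappa shape indices, the Bertz complexity index,
and bridgehead and spiro atom counts — plus nine further standard
descriptors chosen to round the registry out to exactly 32 (aromatic,
saturated and aliphatic heterocycle counts, amide bonds, Hall-Kier alpha,
Labute approximate surface area, Balaban J, and the valence connectivity
indices Chi0v and Chi1v). The registry is fixed and named
(`compute_physchem()` returns named columns), because the 544-length
contract is load-bearing downstream. All chemistry — parsing,
canonicalization, descriptor and fingerprint computation, graph perception
— is delegated to RDKit through a bundled Python helper, called once per
batch of molecules; the package never re-implements chemical perception.

## Data cleaning

`clean_activities()` applies, in order: SMILES validation (multi-fragment
inputs are reduced to their largest fragment by heavy-atom count, counted
but not dropped), removal of rows with non-numeric values or a standard
type other than IC50, unit harmonisation (nM kept, uM converted at 1000
nM/uM, anything else dropped), removal of nonpositive concentrations (they
cannot be log-transformed), median collapse of duplicate (canonical SMILES,
target) pairs — the arithmetic mean of the two central values for even
group sizes — and finally the log10 transform. Every dropped row is
tallied by stage, and the invariant `n_raw = n_clean + sum(drops)` is
asserted in the tests on every input.

Splitting is record-level by default, matching how pooled multi-target data
are usually split: the same compound may then sit in train for one target
and in test for another, which leaks compound identity across the split.
`split_activities(by_compound = TRUE)` provides the stricter compound-level
alternative; it is off by default for fidelity to the pooled-table
protocol. Note also that the pooled model receives no target identity
feature: identical compounds measured against different targets carry
different labels, and that label conflict is an irreducible error floor for
this design — the package implements exactly this and does not invent a
target embedding.

Oversampling (`oversample_by_target()`) draws records with replacement,
seeded, until every target matches the largest target's count, keeping all
originals; it is drawn once per training run, not per epoch.

## Training

Smooth-L1 (Huber) loss with transition beta = 1 log unit, Adam at learning
rate 1e-3 with L2 weight decay 1e-5, batch size 32, 300 epochs by default,
no early stopping and no learning-rate schedule. Test-set metrics are
logged per epoch for curve inspection only; nothing is selected on them,
and headline metrics are final-epoch metrics.

Two numerical choices matter in practice and are on by default in
`train_control()`:

* **Output-bias initialization.** The response lives around 2-5 log10 nM,
  far from zero. Since Adam moves each parameter by at most about the
  learning rate per step, starting the output bias at zero wastes thousands
  of steps locating the intercept. The final bias therefore starts at the
  training-label mean.
* **Batch-norm refresh.** During training, batch normalization uses
  mini-batch statistics and keeps exponential running averages (momentum
  0.1) for eval mode. With small batches those averages lag the last noisy
  mini-batches and eval metrics jitter. After the last epoch the running
  statistics are recomputed in one pass over the training set (dropout
  off), so eval-mode predictions reflect full-sample statistics.

Other numerical details: batch normalization uses biased (1/n) variance
with eps = 1e-5; a mini-batch of size 1 would make batch statistics
degenerate, so a trailing singleton batch is folded into its predecessor;
the z-score normalizer guards zero-variance dimensions (fingerprint bits
that never fire in a small training set) by mapping them to 0 with an
eps = 1e-8 denominator floor; dropout is inverted (scaled at train time);
attention uses LeakyReLU slope 0.2 with a per-receiver max-subtraction
before the softmax exponential. All randomness (initialization, shuffling,
dropout, oversampling) is driven by explicit seeds, and training is
bit-reproducible for a fixed seed.

## Where the design was genuinely open

* *"Hidden dimension 128 with two heads"* admits two readings; per-head
  width 64 concatenated to 128 is used, because 2 x 128 heads would pool to
  a 512-dimensional readout, contradicting the declared 256.
* Activation / normalization / dropout order inside a block is
  ReLU -> batch norm -> dropout, following the listed order of the
  components.
* The element-hybridization identity is kept as a single categorical
  column in the 11 node features and embedded inside the model (a learned
  table), rather than one-hot encoded into the feature matrix.
* Bond type and bond stereo are ordinal codes (single/double/triple/
  aromatic = 1-4; stereo enumeration with 0 = none), keeping exactly 5 edge
  columns.
* Molecular size sums heavy-atom atomic numbers only; implicit hydrogens
  are excluded (they are already counted in a node feature). mol_size is
  fed raw, outside the normalized 544-vector.
* Chirality flags come from CIP assignment; undetermined centers leave
  both flags 0.
* Smallest-ring size follows the smallest-set-of-smallest-rings convention.

## The synthetic-data generator

Tests and the acceptance script run entirely on synthetic data, generated
by a fixed fragment grammar: scaffold templates (benzene, pyridine, furan,
thiophene, naphthalene, cyclohexane, piperidine, THF, chains, amides, two
chiral templates) with drug-like substituents (alkyl, halogen, hydroxyl,
amine, carboxyl, nitrile, trifluoromethyl, methoxy). Every generated string
is valid by construction; molecules are unique as canonical SMILES.
Activity tables plant a known signal:

* **descriptor mode** — log10 IC50(nM) = 3 + w' z(descriptors) + target
  offset + N(0, noise_sd), with default weights LogP +1.0, TPSA -0.8, ring
  count +0.5 on within-set standardized descriptors, target offsets an
  equispaced ladder in [-0.25, +0.25], and noise_sd 0.3 — the intercept
  puts the median compound at 1 uM and the noise at a typical inter-assay
  reproducibility scale;
* **substructure mode** — a +2 log-unit shift for molecules carrying a
  marker substituent (chlorine by default, present in about half the
  molecules), visible to the graph branch but deliberately planted on
  structure rather than on a tabulated descriptor.

Both modes emit values in mixed nM/uM units and can append duplicate rows
with jittered values and deliberately invalid rows (malformed SMILES,
nonpositive or missing values, unknown units, non-IC50 types), each labelled
with the cleaning stage expected to drop it, so provenance accounting is
testable row by row.

What the generator does *not* emulate: real assay noise structure
(heteroscedastic, censored, inter-laboratory), the chemical space of any
real target, activity cliffs, and scaffold-biased train/test similarity.
Passing the synthetic checks therefore demonstrates that the pipeline,
featurization, network and optimizer are correct and can recover known
structure-activity signal — not that the architecture attains any
particular accuracy on real ChEMBL targets. Reproducing published-scale
results requires a ChEMBL download (about 14k compounds over nine targets)
and full 300-epoch training, which the command-line interface supports
(`ic50net run-all`) but the test suite deliberately does not attempt.

## Problem sizes used by the checks

The shipped checks use desk-scale conditions chosen once: a 32-molecule
single-target set for the memorization (capacity) check — run with the
default widths but dropout disabled, since a capacity check measures what
the architecture can fit, not what the regularizer prevents — trained
full-batch for 300 epochs; and 1000-molecule three-target fixtures (800
train / 200 held out, noise 0.3) for signal recovery, trained 40 epochs
(descriptor mode, full model) and 60 epochs (substructure mode, descriptor
branch ablated). Held-out R2 stabilizes well before those epoch counts on
these fixtures.

## Known limitations

* Strictly 2D topology: no conformers, no 3D descriptors, no partial
  charges; conformation-sensitive targets will be harder.
* No target-identity input: pooled multi-target training relies on
  chemistry alone, with the label-conflict floor described above.
* Record-level splitting leaks compound identity across targets by
  default (documented switch for compound-level splits).
* The nine registry fill-in descriptors are this package's documented
  choice of standard descriptors; other implementations may fill the
  32-slot registry differently.
* Training runs on CPU in plain R; it is comfortable at thousands of
  molecules but not intended for hundred-thousand-compound screens.
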