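# ic50net

Hybrid graph-attention / descriptor regression of small-molecule potency
(log10 IC50) from SMILES, for cheminformaticians and computational
medicinal chemists doing ligand-based QSAR on ChEMBL-style activity tables.

## The model

Two parallel encoders, fused:

* **Graph branch.** The molecule is a graph whose node identity is the
  *element-hybridization tuple* — Csp3 and Csp2 are distinct vocabulary
  entries — embedded in a learned table and concatenated with 10 numeric
  atom features (11 node features total; 5 bond features per edge). Two
  edge-conditioned multi-head graph-attention layers (hidden width 128,
  2 heads, ReLU + batch norm + dropout 0.2) are read out by concatenated
  global mean and max pooling into a 256-dimensional embedding.
* **Descriptor branch.** A 544-vector per molecule — 512-bit Morgan
  fingerprint (radius 2) followed by 32 physicochemical descriptors —
  z-scored on training statistics and encoded 544 → 256 → 128 (dropout 0.3).
* **Fusion.** [graph 256 ‖ descriptors 128 ‖ molecular size 1] = 385 → 64 →
  1, giving the predicted log10 IC50 in nM (lower = more potent).

Training minimizes smooth-L1 (Huber) loss with Adam (lr 1e-3, weight decay
1e-5), batch size 32, with seeded train/test splitting and per-target
oversampling. The cleaning pipeline validates SMILES, harmonises nM/µM
units, drops nonpositive values, collapses duplicate (compound, target)
pairs to the median, log-transforms, and accounts for every dropped row.

Chemistry (parsing, canonicalization, descriptors, fingerprints, graph
perception) is delegated to RDKit via a bundled Python helper; the network,
training loop and pipeline are plain R.

## Worked example

Everything below runs offline on synthetic molecules with a planted
structure–activity signal:

```r
library(ic50net)

spec  <- fixture_spec(n_molecules = 1000, n_targets = 3, noise_sd = 0.3,
                      dirty_fraction = 0, dup_fraction = 0, seed = 17)
raw   <- generate_activity_table(spec)   # ChEMBL-shaped rows, mixed nM/µM
clean <- clean_activities(raw)
print(clean)
#> <clean_dataset> 1000 samples from 1000 raw rows (3 targets)
#>   dropped: invalid_smiles=0, bad_value=0, bad_units=0, nonpositive=0, duplicates=0

sp  <- split_activities(clean, test_fraction = 0.2, seed = 42)
fit <- ic50net(sp$train, test = sp$test,
               control = train_control(epochs = 40, seed = 42, eval_every = 10))
print(fit)
#> Hybrid graph-attention + descriptor IC50 model
#>   training samples: 800 (3 targets)
#>   epochs: 40, batch size: 32, final train loss: 0.1142
#>   train:  R2 = 0.990, RMSE = 0.177, MAE = 0.138 (log10 nM)
#>   test:   R2 = 0.922, RMSE = 0.483, MAE = 0.377 (log10 nM)

predict(fit, c("CCO", "Clc1ccc(CC(C)C)cc1"))   # log10 IC50 (nM) for new SMILES
#> [1] 0.413026 5.347039
summary(fit)        # per-target R2 / RMSE / MAE tables
plot(fit)           # loss / R2 / RMSE training curves
plot(fit, "fit")    # predicted vs observed scatter
```

The test R² ≈ 0.92 means the model recovered the planted
descriptor-linear signal (noise SD 0.3 log units caps attainable R² near
0.94 on this fixture); RMSE/MAE are in log10 nM units, and the train/test
gap reflects ordinary finite-sample overfitting under dropout and weight
decay. On real pooled
ChEMBL data the attainable numbers depend on the targets, the database
version and full-length (300-epoch) training.

A command-line interface wraps the same functions:

```sh
inst/cli/ic50net make-fixtures --out raw.csv --n 200 --seed 42
inst/cli/ic50net prepare --in raw.csv --out clean.csv
inst/cli/ic50net run-all --in raw.csv --out run/ --epochs 50 --seed 42
inst/cli/ic50net predict --model run/model.rds --smiles-file in.smi --out preds.csv
```

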