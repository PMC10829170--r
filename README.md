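# contrastDDI

Self-supervised molecular representations for drug–drug interaction (DDI)
side-effect prediction, in R.

Labeled drug-pair interaction data are scarce and heavily imbalanced, while
unlabeled molecules are abundant. `contrastDDI` addresses this with a
two-stage transfer pipeline for cheminformatics and drug-safety
researchers:

1. **Contrastive pre-training.** One molecule admits many valid SMILES
   spellings. The package enumerates randomized spellings by permuting the
   molfile atom order and trains a 1D-convolutional encoder so that the
   canonical and a randomized spelling of the same molecule agree. With a
   minibatch of m molecules (2m views) and projections z, the InfoNCE loss
   for a positive pair (i, j) is

   ```
   L(i,j) = -log( exp(sim(z_i, z_j)/τ) / Σ_{k≠i} exp(sim(z_i, z_k)/τ) )
   ```

   with `sim` the cosine similarity and τ a temperature, averaged over all
   2m ordered pairs. The encoder is token embedding (148-token vocabulary,
   width 116) → conv1D stack → global max-pool → a 262-wide representation
   h, with a two-layer projection head used only during pre-training.

2. **Transfer.** Each drug of a pair is embedded with the frozen encoder,
   the pair is represented as the concatenation [h1 ‖ h2] (width 524), and
   a feed-forward classifier is trained with the negative log-likelihood
   objective under one of three class-imbalance samplers (balanced batches,
   class weighting, weighted random). Three evaluation schemes quantify
   generalization: random stratified 80:10:10, one-unseen (test pairs have
   exactly one drug never seen in training) and both-unseen (both drugs
   new).

Around the model, the package implements the scaffold-level dataset
analyses the approach is motivated by: Bemis–Murcko scaffold extraction,
FP-Growth frequent scaffold-pair mining with association rules
(support/confidence/lift), binary scaffold interaction / side-effect
profile matrices with single-linkage Jaccard clustering, a five-metric
binary similarity suite (Tanimoto, Dice, Kulczynski, Asymmetric,
Rogot–Goldberg), and the dataset-diversity metrics SNN and Scaff. A
synthetic-data generator produces scaffold-structured molecule libraries
and DDI tables so the entire pipeline runs offline.

Chemistry (parsing, canonical SMILES, ECFP fingerprints) is handled through
OpenBabel via `ChemmineOB`; the neural networks, the contrastive objective
and the mining algorithms are implemented in the package and tested against
independent brute-force oracles.

## Worked example

```r
library(contrastDDI)

fc    <- fixture_config(seed = 1)            # 8 scaffold families x 25 molecules
lib   <- generate_molecule_library(fc)
pairs <- generate_ddi_dataset(lib, fc)       # 2000 pairs, 6 imbalanced classes
table(pairs$label)
#>   0    1    2    3    4    5
#> 991  504  253  130   76   46

cfg <- encoder_config(conv_channels = c(64L, 96L, 128L),
                      kernel_sizes = c(5L, 5L, 3L), max_len = 48L)
st  <- pretrain(lib, cfg, epochs = 10, batch_size = 32, seed = 7,
                pool_size = 20)
tail(st$history, 1)
#> epoch 10: train 2.433  val 2.267  acc_top1 0.575
```

The validation `acc_top1` of 0.575 means that for 57.5% of held-out
molecules the randomized spelling is the single nearest neighbor of the
canonical spelling among all held-out candidates (chance level here is
1/64 ≈ 0.016) — the encoder has learned view-invariant molecule identity.

```r
sp   <- stratified_random_split(pairs, seed = 0)
ccfg <- classifier_config(hidden_dims = c(256L, 128L), n_classes = 6L,
                          batch_size = 128L, epochs = 20L)
fit  <- train_and_evaluate(pairs[sp$train_ids, ], pairs[sp$val_ids, ],
                           pairs[sp$test_ids, ], encoder = st,
                           config = ccfg, seed = 0)
fit$reports$test
#> <metric_report: acc 0.835, F1w 0.839, Pw 0.857, Rw 0.835, AUROC 0.974, AUPRC 0.914>
```

The report gives support-weighted accuracy/precision/recall/F1 and
macro-averaged AUROC/AUPRC over the six side-effect classes; here the
frozen pre-trained representation supports a weighted F1 of 0.84 on
held-out pairs after ten pre-training epochs.

```r
freq <- fp_growth(pair_transactions(pairs), min_support = 0.02)
nrow(freq)           # 34 frequent scaffold itemsets
freq[1, ]            # most frequent: the furan family, support 0.233
rules <- association_rules(freq, min_confidence = 0.5)
```

A command-line front end over the same functions ships in
`inst/cli/contrastDDI.R` (subcommands `fixtures`, `pretrain`, `split`,
`train-ddi`, `analyze`).

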