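---
title: "Methods: contrastive SMILES representations for DDI side-effect prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrastive SMILES representations for DDI side-effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Predicting which side effect a pair of drugs will produce when taken
together is a multiclass classification problem over drug pairs. Labeled
interaction data are scarce relative to chemical space, so the package
follows a two-stage transfer strategy: first learn a general-purpose
molecular representation from unlabeled molecules with self-supervised
contrastive learning, then train a small supervised classifier on pair
representations. The self-supervision signal comes from *SMILES
enumeration*: one molecule admits many valid SMILES spellings, and two
spellings of the same molecule are a natural positive pair.

## The contrastive objective

Given a minibatch of m molecules, each contributes two views — its
canonical SMILES and one randomized spelling — for 2m views in total.
Each view is encoded to a projection z, and for a positive pair (i, j)
the per-pair loss is

    L(i, j) = -log[ exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau) ]

where `sim` is the cosine similarity (bounded in [-1, 1]) and `tau` a
temperature. The reported batch loss averages the per-pair loss over all 2m
ordered pairs (both (i, j) and (j, i)), the symmetric convention of the
SimCLR family, which reduces to the per-pair definition above for each
ordered pair. Losses are computed with max-subtraction log-sum-exp; cosine
similarities are clamped to [-1, 1] against floating-point rounding, and a
zero-norm projection raises an error rather than propagating NaN.

When every projection is identical the loss equals `log(2m - 1)` for any
temperature, and with m = 1 it is identically 0 — both are used as test
oracles, alongside a brute-force double-loop implementation.

### Temperature

The temperature default is `tau = 0.1`. The choice was made on
representation-quality diagnostics on the synthetic library: validation
view-retrieval accuracy (`top1_accuracy`) and the effective rank of the
representation matrix (the participation ratio of its singular values).
Higher temperatures (0.5–1.0) produced markedly collapsed representations
(effective rank < 3 out of 262) on small training sets; `tau = 0.1` kept
both retrieval accuracy and rank substantially higher. The parameter is
exposed in `encoder_config()`.

## Encoder architecture

The encoder e(.) maps a fixed-length token sequence to a representation h:

* token embedding, 148-token vocabulary, width 116;
* a stack of 1D convolutions (default channels 128/192/256, kernels
  5/5/3), each followed by batch normalization, ReLU and dropout (0.1);
* global max pooling over sequence positions — chosen for robustness to
  sequence length, since SMILES of very different lengths must map to one
  fixed-width vector;
* a linear map to the transferred representation h of width 262.

The projection head g(.) is a two-layer fully connected network
(262 → 256 → 128); the contrastive loss is applied to z = g(h), and h is
what is transferred downstream. Vocabulary size, embedding width and
representation width are treated as framework constants; everything else is
configurable. All forward/backward passes, AdamW (decoupled weight decay)
and the cosine-annealed learning-rate schedule are implemented in plain R
matrix code, with gradients verified against central finite differences in
the test suite.

## SMILES enumeration

Randomized views are produced exactly the way the underlying augmentation
is defined: the molecule is converted to a molfile block, its atom order is
permuted with a seeded RNG, and a (non-canonical) SMILES is re-emitted from
the permuted block through OpenBabel. Every view canonicalizes back to the
parent molecule — a property asserted for the whole fixture library. At
most 50 distinct views are kept per molecule (`options(contrastDDI.view_cap)`),
and pre-training draws each epoch's view from this pre-enumerated pool with
a per-epoch derived seed, so "fresh enumeration every epoch" is exactly
reproducible under one master seed.

OpenBabel silently repairs unbalanced parentheses, so `canonicalize()`
performs a bracket-balance check first; everything else that OpenBabel
rejects surfaces as a structured `parse_error`.

## Tokenization

The vocabulary is frozen in a shipped plain-text file: 118 element symbols,
the aromatic atoms b/c/n/o/p/s, ring digits 0–9, brackets, the bond and
charge symbols (including `@` and `\`), `%`, and a `<pad>` token — 148
entries. A purely per-character scheme cannot represent two-letter elements
(Cl, Br, Si, ...), so encoding is greedy longest-match: a two-character
element symbol is consumed whenever it matches, else one character. This
can read an S followed by an aromatic c as "Sc"; the encoding still
round-trips to the exact input string, which is the property the encoder
relies on. Sequences are padded to a fixed `max_len` (default 250, covering
the bulk of typical small-molecule SMILES); longer inputs are truncated to
the prefix with a warning. Dot-disconnected (multi-fragment) SMILES are out
of scope, consistent with the absence of salt handling.

## Pre-training protocol

Molecules are split 80:20 with the greedy MaxMin diversity picker on ECFP
(radius 2, 2048 bit) Tanimoto distance, the 20% diverse side serving as
validation. Optimization uses AdamW (lr 1e-3, weight decay 1e-6) with
cosine annealing over the epoch budget. Per-epoch history records training
loss, validation loss and validation `top1_accuracy` (the fraction of
anchors whose own alternative view is the strict nearest neighbor — ties
count as failures); the checkpoint with the lowest validation loss is the
one transferred.

## Transfer to DDI prediction

Every distinct drug is embedded once with the frozen encoder; a pair is
represented by the concatenation [h1 || h2] (order-sensitive; an optional
`symmetrize_pairs` flag trains on both orders). A feed-forward classifier
(default 1024 → 512 → C, dropout 0.2) is trained with the negative
log-likelihood objective, batch size 256, and the epoch with the best
validation weighted F1 is kept for inference.

The concatenated representations are fed to the classifier **as-is**. An
optional `standardize` flag can z-score the features, but it is off by
default: the conditioning of the learned representation is part of what the
pre-training ablation measures, and normalizing it away artificially
flatters a randomly initialized frozen encoder.

Three imbalance-handling samplers are provided: `balanced_batch`
(per-class counts within one of each other in every batch, minorities
resampled with replacement; more classes than batch slots degrade to a
rotating one-per-class coverage), `class_weight` (inverse-frequency example
weights aggregated per class — classes drawn uniformly, then an example
uniformly within the class) and `weighted_random` (examples drawn with
replacement with weight 1/class-frequency).

## Evaluation schemes and metrics

* **Random split** — stratified 80:10:10 by class; all drugs seen in
  training.
* **One-unseen** — a fraction of drugs (default 10%) is held out as "new";
  test pairs contain exactly one new drug.
* **Both-unseen** — test pairs contain two new drugs. Both cold-start
  schemes share the identical training set, validation is carved from
  known-drug pairs only, and every input pair lands in exactly one bucket.

Accuracy, precision, recall and F1 are computed per class one-vs-rest and
support-weighted; AUROC (via pROC) and AUPRC (step-sum average precision)
are macro-averaged. Classes absent from the evaluated truth vector are
excluded from the averages (skipped, not zero-filled, to avoid deflating
macro curves with undefined entries) with a logged note.

## Scaffold-level analyses

Bemis–Murcko scaffolds are computed on the molecular graph: the 2-core of
the bond graph (iteratively stripping terminal atoms) is exactly the ring
systems plus inter-ring linkers; atoms attached to that core by a double or
triple bond (exocyclic carbonyls and the like) are retained, and the
scaffold substructure is re-emitted as canonical SMILES. Acyclic molecules
have no scaffold and form a single "(acyclic)" family downstream. The
implementation is validated against an independent reference decomposition
on a 20-molecule battery in the test suite.

Frequent scaffold combinations are mined with FP-Growth (conditional
FP-tree recursion) and cross-checked itemset-for-itemset against a
brute-force Apriori enumeration. Association rules enumerate every
non-trivial bipartition of each frequent itemset with support, confidence
and lift. Because it is ambiguous whether transactions should carry the
side-effect label as an item, `pair_transactions()` supports both
encodings via `include_label`.

Binary profile matrices record the *presence* of a scaffold–scaffold
interaction (directional: position-1 rows × position-2 columns, with an
optional symmetrized view) or a scaffold–side-effect association; counts
are deliberately binarized to remove frequency bias. Rows are clustered by
single-linkage on Jaccard distance and cut with the depth-2 inconsistency
criterion (threshold 1.0 by default — the documented default of the
reference hierarchical-clustering routine); identical profiles always
co-cluster, and all-zero rows (undefined Jaccard) become singletons with a
warning. Cluster structure is summarized with a five-metric binary
similarity suite (Tanimoto, Dice, Kulczynski, Asymmetric, Rogot–Goldberg)
as average intra- versus inter-cluster pairwise similarity.

Dataset-diversity metrics: SNN (mean Tanimoto similarity of each query
molecule to its nearest reference neighbor) and Scaff (cosine similarity of
two sets' scaffold-frequency vectors; the "(acyclic)" family counts as one
shared bucket).

## The synthetic-data generator

`generate_molecule_library()` decorates up to ten ring-system templates
(benzene, pyridine, naphthalene, cyclohexane, piperidine, thiophene,
furan, pyrrole, tetrahydropyran, pyrimidine) with a fixed list of small
substituents at two sites, canonicalizes and de-duplicates, and draws a
seeded per-family sample; by construction every molecule's Murcko scaffold
is its template's scaffold. Defaults: 8 families × 25 molecules = 200
molecules.

`generate_ddi_dataset()` assigns each unordered scaffold-family
combination one side-effect class through a seeded lookup, samples pairs so
class frequencies follow a geometric profile (`imbalance_decay^k`, default
decay 0.5 over 6 classes, emulating a heavily skewed side-effect
distribution), and flips a label to a random other class with probability
`label_noise` (default 0.02). Labels depend on scaffold *pairs*, not on
individual molecules, so a representation that clusters molecules by
scaffold is genuinely useful — the premise the transfer experiment probes.

What the generator does **not** emulate: real pharmacological label
taxonomies, stereochemistry, salts, molecules without any learnable
scaffold→label relationship, or SMILES longer than a few dozen tokens.
Passing tests on fixtures therefore demonstrate internal correctness and
the direction of the method's effects, not clinical-scale performance.

## Problem sizes in the shipped tests

The test suite trains at desk scale by choice: smoke pre-training uses the
200-molecule default library, 30 epochs, batch 32, a 48-token window and a
reduced convolution stack (64/96/128); the transfer ablation runs 5
stratified seeds of a 2000-pair benchmark with a 256/128 classifier for 20
epochs; the diversity contrast compares 2 × 40 against 8 × 10 molecules at
equal epoch budgets. The package defaults remain at the full-scale values
documented above.

## Known limitations

* OpenBabel's canonical SMILES is the package's molecule-identity oracle;
  canonical strings differ from other toolkits' spellings (equality is
  well-defined only within one toolkit).
* The Murcko implementation handles kekulized single-fragment organic
  molecules; exotic aromatic typing (e.g. [se]) is outside the tokenizer's
  single-character aromatic set.
* ECFP fingerprints come from OpenBabel's 4096-bit hashed sets folded to
  the requested width; bit positions are not comparable with other
  toolkits' ECFP implementations, though similarity values behave
  equivalently.
* Training is single-threaded CPU R; it is meant for method-scale
  experiments, not for pre-training on hundreds of thousands of molecules.
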