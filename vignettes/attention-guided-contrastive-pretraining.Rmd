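---
title: "Attention-guided contrastive pretraining for SMILES property prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided contrastive pretraining for SMILES property prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claps)
```

## The model

`claps` implements self-supervised pretraining of a SMILES-string encoder in
which the *positive view* of each molecule is produced by masking characters
that a trainable attention network considers important, followed by
supervised fine-tuning for molecular property prediction.

**Tokenization and input features.** A SMILES string is split into tokens:
bracket atom expressions (`[NH+]`, `[C@@H]`), the two-letter halogens `Cl`
and `Br`, two-digit ring closures (`%nn`), and every other character singly.
Treating `Cl` as one token matters: splitting it would invent a carbon atom.
The vocabulary is built in first-appearance order over the pretraining
corpus, with `<pad>` and `<mask>` appended. Each token id indexes a row of a
trainable embedding table initialized from N(0,1); the embedded sequence
`S` (fixed length `C`, pad-filled) is added elementwise to the standard
sinusoidal position matrix `P` (`sin(pos/10000^(2i/d))`,
`cos(pos/10000^(2i/d))`), giving the encoder input `X = S + P`.

**Positive-sample selection (PSS).** A separate multilayer multi-head
self-attention network scores each character: head `i` computes
`Att_i = softmax(X Wq_i (X Wk_i)^T / sqrt(d))` over the non-pad positions,
and the weight of position `r` is the double sum
`w_r = sum_i sum_c Att_i[r, c]`. Because every attention row is a
probability vector, `sum_r w_r = heads * L` exactly — a conservation law the
tests assert. Three strategies turn weights into a mask of
`ceil(ratio * L)` positions:

* **roulette** (default, ratio 0.25): positions drawn sequentially without
  replacement with probability proportional to the remaining weights. A
  frequency-based variant (`roulette_occurrence = TRUE`) uses token
  occurrence counts `f_i / sum f` instead, for users who prefer the
  character-frequency reading of roulette selection; the attention-weight
  form is the default since attention guidance is the method's point.
* **top**: the `ceil(ratio * L)` largest weights, ties broken toward the
  lower position index.
* **random**: a uniform sample, the ablation baseline.

Masked positions are *replaced* by the `<mask>` token (never deleted), so
sequence length and positional alignment are preserved.

**Encoder and projection.** The encoder is a 3-layer transformer, each layer
a 4-head self-attention sublayer and a two-linear ReLU feed-forward sublayer
(inner width `4d`), each wrapped as `LayerNorm(x + Dropout(sublayer(x)))`.
Attention and pooling are restricted to non-pad positions, so pad content
can never influence the representation (asserted to 1e-6 in the tests). The
molecule representation `h` is the mean over non-pad positions — the
simplest pad-robust pooling; no CLS-style token exists in this vocabulary —
with `pool = "sum"` available (see fine-tuning below). A bias-free
two-layer perceptron `z = ReLU(h W2) W1` (default widths 2048, 512) maps
`h` to the projection space used only during pretraining.

**Contrastive objective.** A minibatch of `N` molecules yields `2N`
projections, interleaved so rows `(2k-1, 2k)` are a positive pair. With
`Sim(z_i, z_j)` the cosine similarity and temperature `T`,

```
l(i, j) = -log exp(Sim(z_i, z_j)/T) / sum_{k != i} exp(Sim(z_i, z_k)/T)
L = (1/2N) sum_k [ l(2k-1, 2k) + l(2k, 2k-1) ]
```

the NT-Xent loss. Analytic anchors used in the tests: a batch of one pair
has loss exactly 0; four mutually orthogonal projections give `log 3` for
every `T`. One Adam step per minibatch (learning rate 1e-3); fresh masks
are drawn every epoch to increase augmentation diversity.

**Prediction stage.** The projection head is dropped (the usual SimCLR
convention; only the encoder feeds prediction). A fully connected head —
default widths (4096, 512, 64), ReLU between layers, linear output of width
= number of tasks — is attached to `h` and the whole network fine-tuned
(learning rate 1e-4 by default; `freeze_encoder = TRUE` trains the head
only). Classification trains with masked binary cross-entropy on sigmoid
outputs; unobserved labels are carried in an observation mask and never
contribute (bit-identical losses under perturbation of unobserved cells).
Regression trains on the RMSE loss directly (its gradient
`r_i / (n · RMSE)` keeps a roughly constant magnitude near the optimum,
which makes the validation curve noisy late in training; the best-epoch
snapshot absorbs that). Regression targets are standardized on the
training subset and predictions mapped back. The epoch
with the best validation metric is kept (patience-based early stopping).
Evaluation is macro-averaged ROC-AUC over tasks with both classes observed
(midrank Mann-Whitney form, ties counted one half), or RMSE.

## Splitting

`scaffold_split()` groups molecules by canonical Bemis-Murcko scaffold
(ring systems plus linkers; terminal atoms double-bonded to the scaffold are
retained; acyclic molecules share the empty scaffold) and assigns whole
groups greedily — largest first, ties by scaffold string — to train, then
valid, then test at 8/1/1. No scaffold ever spans subsets, which makes the
test set structurally disjoint from training and deliberately harder than
`random_split()`. The greedy assignment is fully deterministic, so the
`seed` argument of `scaffold_split()` is accepted only for interface parity.
Note that strict scaffold *equality* is used: benzene and naphthalene have
different Murcko scaffolds and may land in different subsets, even though
both are plain ring systems; a coarser "ring-system family" grouping would
need a similarity threshold this package deliberately avoids.

Chemistry perception — SMILES parsing, validity, canonical SMILES — is
delegated to OpenBabel (via ChemmineOB). The Murcko pruning itself operates
on the V2000 MOL-block graph in R, and the pruned subgraph is
re-canonicalized by OpenBabel so scaffold identity is string equality.
Scaffold strings drop stereochemistry.

## The synthetic-data generator

`generate_synthetic_corpus()` emulates a desk-scale drug-like chemical
space: linear C/N/O/S chains with occasional methyl branches and halogen
terminals, and molecules carrying one or two aromatic rings (five benzene-
and pyridine-like 6-rings, six furan/thiophene/pyrrole-like 5-rings) joined
by 0-3 carbon linkers. At `n = 1000` this yields well over 50 distinct
Murcko scaffolds, enough for scaffold splitting to be meaningful. Defaults
(committed once, before any training experiment): `max_atoms = 12`.

`generate_synthetic_labels()` plants recoverable structure:

* **classification**: the indicator of an element motif, flipped with
  probability `noise` (default 0.05). The default motif is *contains
  sulfur*, whose prevalence in the committed grammar is ~0.46. The motif
  must be near-balanced: with prevalence `p` and flip rate `e`, the best
  achievable test ROC-AUC for *any* classifier is bounded by the posterior
  overlap of flipped labels, and at `p = 0.8, e = 0.05` that ceiling is
  ~0.88 — no implementation could demonstrate signal recovery at the 0.9
  level. At `p = 0.46` the ceiling is ~0.95.
* **regression**: the linear atom-count rule
  `y = n_C + 2 n_N + 3 n_O + 4 n_S + n_halogen + N(0, noise^2)`, noise
  default 0.1. Counts are *extensive* quantities: a mean-pooled
  representation cannot express them (it loses sequence length), so
  regression experiments in this package run the encoder with
  `pool = "sum"`. This is a representational-capacity argument, not a tuning
  knob: the sum over non-pad positions of per-position features is the
  minimal pooling under which a weighted atom count is linearly readable.

What the generator does **not** emulate: stereochemistry and charged bracket
atoms (parsed, but never generated), macrocycles and fused or aliphatic
rings, realistic functional-group co-occurrence, and any property whose
signal lives in 3D geometry. Passing the planted-signal tests therefore
shows that the pipeline can learn string-expressible structure through the
full pretrain-finetune path; it does not certify performance on real
benchmark chemistry.

## Numerical and design choices

* **Fixed length `C`**: default 220, covering typical drug-like SMILES;
  over-length strings are a hard *error* in `encode()` (silent truncation
  would corrupt a contrastive pair), but corpus/dataset loaders drop such
  rows with a logged count.
* **Attention scaling**: scores divided by `sqrt(d)` (PSS, with `d` the
  model width as the weight matrices are `d x d_k`) and `sqrt(d_k)` per
  head in the encoder.
* **PSS depth**: "multilayer" with no count given; two layers, the smallest
  honoring the plural. A PSS layer has no value matrices, so layer `l+1`
  consumes the head-averaged mixture `mean_i(Att_i X)`; the final layer's
  attention is what the weight vector aggregates.
* **PSS training**: mask selection is discrete sampling, so no gradient
  path exists from the contrastive loss to the PSS parameters; they remain
  at their seeded initialization. The attention guidance is therefore a
  structured random scorer in this implementation — any scheme for training
  it would have to invent an objective the method does not define.
* **Temperature**: nowhere specified by the method; default `T = 0.1`,
  exposed prominently in the configuration.
* **Masked count**: `ceil(ratio * L)`, so any positive ratio masks at least
  one character.
* **Ties in top-masking**: lower position index wins (stable order).
* **Degenerate inputs**: all-zero weight vectors are an error for roulette;
  `L = 1` attention is the 1x1 matrix [1]; batch size below 2 is an error
  for pretraining (the NT-Xent denominator would be empty of negatives).
* **Dropout**: rate 0.2 after each sublayer during training, disabled at
  evaluation; all randomness (initialization, shuffling, masking, dropout)
  runs through R's RNG under the configured seed, so identical
  configurations reproduce identical loss traces bit for bit.
* **Early stopping**: best validation epoch, patience 10 (default).

## Desk-scale problem sizes

The package's own experiments (tests and the acceptance script) run a
reduced geometry chosen for single-CPU sessions: `d = 32`, `C = 80`,
the full 3x4-head encoder, projection (64, 32), predictor (64, 32, 16) —
proportional scale-downs of the published (2048, 512) and (4096, 512, 64) —
batch 64, 5 pretraining epochs on a few hundred generated molecules, and
fine-tuning on 600 labeled molecules under an 8/1/1 scaffold split.
Classification fine-tunes at learning rate 1e-3 with patience-10 early
stopping; regression at 2e-3 for a full 250-epoch budget with best-epoch
snapshotting, because the RMSE-loss validation curve is noisy and
patience-based exits fire on plateaus well before the best epoch. Package
defaults keep the published full-scale values; nothing in the
implementation depends on the reduced sizes.

## A worked example

```{r example, eval = FALSE}
cfg <- claps_config(d = 32L, C = 80L, proj_dims = c(64L, 32L),
                    predictor_widths = c(64L, 32L, 16L), batch = 64L,
                    epochs_pretrain = 5L, lr_finetune = 1e-3,
                    epochs_finetune = 60L, patience = 10L, seed = 21L)
corpus <- generate_synthetic_corpus(400, seed = 100)
pre <- claps_pretrain(corpus, cfg)

smiles <- generate_synthetic_corpus(600, seed = 101)
ds <- generate_synthetic_labels(smiles, "classification", noise = 0.05,
                                seed = 102)
sp <- scaffold_split(ds)
fit <- claps_finetune(ds, sp, pre$model, cfg)
fit$report
```

## Known limitations

* Pure-R training: practical corpus sizes are thousands, not the hundreds
  of thousands the method was designed around; no GPU path.
* The PSS network is untrained (see above), so "attention-guided" masking
  reflects a fixed random attention pattern rather than a learned one;
  roulette and top masking still differ from random masking through the
  weight structure.
* Scaffold grouping is strict string equality of canonical Murcko
  scaffolds.
* The synthetic grammar covers a narrow slice of chemistry (see above);
  conclusions about real MoleculeNet-style data require real data.
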