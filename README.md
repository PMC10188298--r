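# claps

Self-supervised molecular representation learning on SMILES strings, with
**attention-guided positive sampling** for contrastive pretraining, and
fine-tuning for molecular property prediction.

## The problem

Labeled molecular property data (toxicity, solubility, binding) is scarce,
while unlabeled molecules are abundant. Contrastive learning pretrains an
encoder on unlabeled molecules by pulling two *views* of the same molecule
together in a projection space while pushing other molecules away; the
quality of the views decides what the encoder learns. `claps` builds the
positive view of a SMILES string by **masking the characters a trainable
self-attention network scores highly**, instead of masking uniformly at
random.

## The method

For an embedded SMILES `X ∈ R^{C×d}` (token embeddings + sinusoidal
positions), a multilayer multi-head attention network produces per-head
matrices

    Att_i = softmax( X Wq_i (X Wk_i)^T / sqrt(d) ),  i = 1..heads (3)

and the per-character weight vector `w_r = Σ_i Σ_c Att_i[r, c]`
(so `Σ_r w_r = heads · L`). A masking strategy — **roulette** (sampling
without replacement ∝ w, the default), **top** (largest weights), or
**random** — replaces `ceil(ratio · L)` characters with `<mask>`
(ratio 0.25 by default). Original and masked views are encoded by a
3-layer, 4-head transformer encoder, mean-pooled over non-pad positions to
`h`, and projected by the bias-free head `z = ReLU(h W2) W1`. A batch of
`N` molecules yields `2N` projections trained with the NT-Xent loss

    l(i,j) = −log [ exp(Sim(z_i,z_j)/T) / Σ_{k≠i} exp(Sim(z_i,z_k)/T) ]
    L = (1/2N) Σ_k [ l(2k−1,2k) + l(2k,2k−1) ]

with cosine similarity `Sim` and temperature `T = 0.1`. For prediction, the
projection head is dropped and a fully connected head (4096, 512, 64 by
default) is fine-tuned with masked binary cross-entropy (classification,
macro ROC-AUC reporting) or RMSE (regression), under Bemis–Murcko
**scaffold splits** (8/1/1; no scaffold spans two subsets) or random splits.

A built-in synthetic-SMILES generator with planted labels (an element motif
for classification, a linear atom-count rule for regression) makes the
whole pipeline testable at desk scale with no external data. See the
vignette `vignettes/attention-guided-contrastive-pretraining.Rmd` for the
model details and every design decision.

## A worked example

```r
library(claps)

cfg <- claps_config(d = 32L, C = 80L, proj_dims = c(64L, 32L),
                    predictor_widths = c(64L, 32L, 16L), batch = 64L,
                    epochs_pretrain = 5L, lr_finetune = 1e-3,
                    epochs_finetune = 60L, patience = 10L, seed = 21L)

corpus <- generate_synthetic_corpus(400, seed = 100)   # 400 SMILES strings
pre <- claps_pretrain(corpus, cfg)
round(pre$loss_trace, 3)
#> [1] 3.881 3.144 2.749 2.495 2.376

smiles <- generate_synthetic_corpus(600, seed = 101)
ds <- generate_synthetic_labels(smiles, "classification", noise = 0.05,
                                seed = 102)            # planted motif labels
sp <- scaffold_split(ds)                               # 480 / 60 / 60
fit <- claps_finetune(ds, sp, pre$model, cfg)
fit$report
#> <claps_report> test roc_auc: macro 0.9439 over 1 task (n_test=60, best epoch 5)
```

The loss trace is the per-epoch mean NT-Xent loss: it falls as the encoder
learns to match each molecule with its masked view. The report's
`macro 0.944` is the test-set ROC-AUC on scaffolds never seen in training —
the planted structural signal survives the 5% label noise (a perfect
motif detector would score ≈ 0.95 under this noise level).

There is also a command line (`inst/cli/claps.R`) with subcommands
`simulate`, `pretrain`, `split`, `finetune`, `predict`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/claps.R", package = "claps"))')
Rscript "$CLI" simulate --n 500 --seed 1 --out corpus.smi
Rscript "$CLI" pretrain --corpus corpus.smi --d 32 --C 80 --batch 64 \
    --epochs_pretrain 5 --seed 7 --out ckpt/
```

Flags mirror `claps_config()` keys; `--config file.yaml` loads a flat YAML
configuration first (see `inst/extdata/example-config.yaml`), explicit
flags win.

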