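# Example flat configuration for the claps CLI.
# Published defaults: roulette masking at ratio 0.25, batch 1500,
# projection head (2048, 512), pretraining lr 1e-3 over 30 epochs,
# prediction lr 1e-4, dropout 0.2, 3-head PSS, 3-layer 4-head encoder.
# The values below scale the model to desk size; delete a key to fall
# back to its default.
strategy: roulette
ratio: 0.25
d: 32
C: 80
batch: 64
temperature: 0.1
epochs_pretrain: 5
proj_dims: [64, 32]
predictor_widths: [64, 32, 16]
lr_pretrain: 1.0e-3
lr_finetune: 1.0e-3
epochs_finetune: 60
patience: 10
dropout: 0.2
seed: 7
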