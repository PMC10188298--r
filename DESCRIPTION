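Package: claps
Title: Contrastive Pretraining of SMILES Transformers with
    Attention-Guided Positive Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-supervised molecular representation learning on SMILES
    strings.  A trainable multi-head self-attention network scores every
    character of a SMILES string, and the scores drive one of three masking
    strategies (roulette, top-k, random) that generate the positive view for
    NT-Xent contrastive pretraining of a small transformer encoder.  The
    pretrained encoder is fine-tuned with a fully connected head for
    multi-task molecular property prediction (binary classification under
    masked binary cross-entropy, regression under RMSE), evaluated with
    macro-averaged ROC-AUC or RMSE under Bemis-Murcko scaffold or random
    splits.  Includes a synthetic SMILES generator with planted,
    structure-dependent labels so the whole pipeline can be exercised and
    tested at desk scale, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
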