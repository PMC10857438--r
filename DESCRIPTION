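Package: sensorclr
Title: Self-Supervised Contrastive Learning for Ambient Smart-Home Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing activities of daily living from ambient
    binary-sensor event streams recorded in smart homes. Reads and writes
    CASAS-style plain-text event logs, extracts windowed summary features,
    and learns activity representations without labels by contrastive
    pre-training of a CNN-LSTM encoder with multiplicative self-attention
    under the NT-Xent loss and sharpness-aware minimization. Downstream
    protocols include linear probing of the frozen encoder, semi-supervised
    fine-tuning at small label fractions, and cross-home transfer. A
    semi-Markov simulator generates CASAS-format logs with known ground
    truth so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
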