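Package: mvldistill
Title: Knowledge-Distilled Masked Vision-Language Pre-Training for Medical Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scale-configurable implementation of masked multi-modal
    pre-training with teacher-student knowledge distillation for medical
    vision-language models. Provides dual-stream transformer encoders with a
    co-attention fusion module, masked language modelling, masked image
    modelling and image-text matching objectives, hidden-state and
    attention-map distillation with uniform teacher-layer mapping, and an
    attention-guided progressive patch-masking schedule. Includes a
    reverse-mode automatic differentiation engine over dense matrices, an
    AdamW optimiser with linear warm-up, a deterministic synthetic
    radiograph-and-caption corpus generator with known salient regions, and a
    command-line interface, so every mechanism can be exercised end to end on
    a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
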