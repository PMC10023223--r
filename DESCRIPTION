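Package: mdmil
Title: Multiplex-Detection Multiple Instance Learning for Whole Slide Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised classification of whole-slide-image feature
    bags by multiplex-detection multiple instance learning. An internal query
    generation module scores instances with a classification head, gates a
    reliable subtype by a confidence factor, and aggregates top-ranked
    projected instance features into per-subtype internal queries. A multiplex
    detection module combines internal and trainable variational queries in a
    dual-query multi-head cross-attention, refines the per-subtype tokens with
    self-attention and feed-forward blocks, and classifies the averaged bag
    representation. Training couples instance-level and bag-level
    cross-entropies with a memory-based contrastive loss over momentum-updated
    class centers. Includes a slide tiling and background-filtering front end,
    a delimited-text bag container, a synthetic heterogeneous-bag generator
    with planted critical instances, and a CPU training loop with exact
    hand-derived gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    pROC,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
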