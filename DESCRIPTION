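Package: idrlm
Title: Generative Language Modeling and Sequence Analytics for Intrinsically Disordered Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for generative modeling of intrinsically disordered protein
    regions (IDRs): curation of IDRs from per-residue AlphaFold pLDDT traces
    (windowed smoothing, three-state classification, region relabeling),
    fill-in-the-middle tokenization over a 27-token alphabet, a decoder-only
    transformer language model (pre-LayerNorm, SwiGLU, rotary position
    embeddings) with hand-written backpropagation, AdamW pre-training with a
    warmup-plus-cosine schedule, temperature sampling in prompted and
    unprompted modes, GRPO reinforcement-learning alignment against a
    pluggable reward model with composite quadratic reward shaping, and a
    suite of disorder-oriented sequence metrics (FCR, NCPR, kappa charge
    patterning, sequence hydropathy decoration, windowed compositional
    entropy, Wasserstein-1 distribution distances, short-linear-motif
    scanning). Includes seeded synthetic-data generators so the whole
    pipeline runs at desk scale without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
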