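Package: lexcat
Title: Lexical Categorization Modeling of Ventral Occipito-Temporal Cortex
    Activation in Visual Word Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the lexical categorization model (LCM) of left
    ventral occipito-temporal cortex activation during visual word
    recognition: orthographic word-likeness estimation (OLD20, Coltheart's
    N, positional n-gram frequencies) against a frequency lexicon,
    binary-entropy lexical categorization difficulty, pseudoword and
    consonant-string stimulus generation, ad hoc implementations of
    competitor neurocognitive models (lexicon search, combination
    detector, engagement-and-effort, interactive account), a benchmark
    registry of published activation contrasts with qualitative model
    scoring, a standardized simulated-versus-observed region-of-interest
    comparison metric, and robustness analyses (lexicon-size sweeps,
    stimulus-subset stability). A seeded synthetic-lexicon generator
    provides a Zipf-distributed frequency list so every stage is testable
    without access to a proprietary film-subtitle frequency corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
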