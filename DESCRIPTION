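Package: mushSTS
Title: Classification and Product Prediction for Mushroom Sesquiterpene Synthases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A curated knowledge base of experimentally characterized
    sesquiterpene synthases (STSs) from mushroom-forming fungi, together with
    the inference chain used to place new candidate enzymes into the four
    basidiomycete STS clades and predict their product profiles. Provides a
    consensus-grammar scanner for the catalytic aspartate-rich and NSE metal
    binding motifs, pairwise-deletion protein distances (p, Poisson, and
    maximum-likelihood distances under the Jones-Taylor-Thornton model),
    Saitou-Nei neighbor joining with column-bootstrap bipartition supports,
    nearest-neighbor and placement-based clade assignment with
    clade-to-cyclization-mechanism annotation, and a deterministic synthetic
    benchmark generator that evolves clade families along random trees under
    the JTT model with planted catalytic motifs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
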