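Package: drembed
Title: Protein Sequence Embeddings for Drug Repurposing Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein sequences as fixed-width numeric vectors
    (mean-pooled one-hot composition vectors, the Sequence Graph Transform, or
    externally supplied embedding matrices), computes cosine distances between
    disease-protein/drug-target pairs, and tests whether known drug-repurposing
    pairs sit significantly closer in embedding space than background protein
    pairs using a size-matched resampled Mann-Whitney U procedure. Includes
    below-mean consensus candidate calling, t-SNE visualisation of embeddings
    by functional class, and a synthetic-study generator with planted
    repurposing pairs of controlled sequence divergence for calibration and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rtsne,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
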