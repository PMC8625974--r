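Package: cernakit
Title: Competing Endogenous RNA Network Inference for Staged Expression Data
Version: 0.1.0
Authors@R:
    person("cernakit", "maintainers", email = "cernakit@example.org",
           role = c("aut", "cre"))
Description: Infers lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    networks from staged bulk expression data. Provides differential
    expression gating with Benjamini-Hochberg FDR control, canonical
    seed-match miRNA target prediction with multi-source intersection,
    Spearman anti-correlation and Pearson co-expression filters, a
    hypergeometric shared-sponge test, subcellular localization gating,
    hub lncRNA identification, hypergeometric set enrichment, and
    short-time-series trend-profile clustering with exact permutation
    significance. Includes a synthetic time-course generator that plants
    ground-truth ceRNA triplets (expression trends, seed sites,
    localization labels) so the full pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
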