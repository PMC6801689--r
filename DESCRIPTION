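Package: ringcensus
Title: RING-Finger Domain Discovery, Classification and Gene-Family Census
Version: 1.0.0
Authors@R:
    person("Sam", "Ellis", email = "sellis@example.org", role = c("aut", "cre"))
Description: Identifies RING (Really Interesting New Gene) zinc-finger domains
    in protein sequences with a variable-gap consensus grammar over the eight
    conserved metal-ligand positions, assigns each domain to one of seven RING
    types (H2, HCa, HCb, v, C2, S/T, G), and flags incomplete domains carrying a
    single metal-ligand substitution. Builds a genome-level census from gene
    models (per-type and per-chromosome counts, multi-domain proteins,
    intronless genes, tandem duplicate clusters), computes metal-ligand spacing
    and positional conservation statistics, and estimates Ka/Ks for duplicate
    coding-sequence pairs with the Nei-Gojobori (1986) method. A synthetic
    proteome generator with planted ground truth makes every pipeline stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    methods,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
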