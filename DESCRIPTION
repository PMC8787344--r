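Package: hicblocks
Title: Dynamic and Static Chromatin Block Detection from Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects conserved (static) and reorganized (dynamic) higher-order
    chromatin blocks between two biological conditions from binned Hi-C
    contact maps. Contact matrices are denoised by network enhancement (a
    graph-diffusion smoother), then jointly decomposed by consensus-regularized
    multiview non-negative matrix factorization solved with hierarchical
    alternating least squares. Per-bin cluster assignments are compared across
    conditions to call contiguous dynamic and static blocks with
    count-difference statistics. Also included are ICE matrix balancing,
    HiC-Pro sparse-format input/output, differential chromatin interaction
    filtering with a distance-stratified z-score, gene and GWAS-locus linking,
    and a synthetic two-condition Hi-C generator with planted domain
    reorganizations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
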