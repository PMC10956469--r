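Package: pbtped
Title: Parentage-Based Tagging Pipelines for Hatchery Broodstock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs multigenerational pedigrees of hatchery salmonid
    broodstock from SNP genotype archives: genotype and metadata quality
    control, identity resolution of repeat and iteroparous spawners by
    near-identical genotype matching and graph connected components,
    likelihood-based parent-pair assignment under a per-gene-copy
    genotyping-error model with Monte-Carlo false-discovery-rate control,
    per-marker Mendelian-incompatibility diagnostics, population-genetic
    summaries (exact Hardy-Weinberg tests, Weir-Cockerham F_ST, PCA), and
    pedigree-derived life-history tables (age at spawning, iteroparity and
    repeat spawning, straying, inversion-karyotype associations). Includes a
    forward simulator of multi-hatchery broodstock programs with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
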