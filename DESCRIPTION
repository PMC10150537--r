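Package: casdms
Title: Deep Mutational Scanning, DNA-Binding Specificity Models, and
    Amplicon Genotyping for CRISPR Nuclease Engineering
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for directed evolution of CRISPR nucleases
    by saturation mutagenesis under bacterial survival selection: NNK
    single-codon library enumeration and codon-level variant calling,
    log-enrichment phenotype scoring between selection rounds with
    synonymous-variant centering and count filtering, additive
    position-by-base mismatch energy-matrix inference from Spec-seq
    (bound/unbound) and SEAM-seq (cleaved/mock) count data with motif-logo
    and MEME export, and genotype classification of diploid T0 plants from
    amplicon allele-frequency tables. A synthetic-data generator simulates
    every assay from known ground truth so each stage of the pipeline is
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
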