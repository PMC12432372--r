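Package: flsubtype
Title: Mutational Signatures, Kataegis Detection, and Genetic Subtyping
    of Follicular Lymphoma Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the genomic characterization of follicular
    lymphoma (FL) whole genomes: 96-channel single-base-substitution catalogs
    and de-novo mutational-signature extraction by non-negative matrix
    factorization (NMF), detection of clustered somatic mutations (kataegis)
    by intermutation-distance Fisher testing with AID/POLH (K1/K2) signature
    decomposition, integer encoding of gene-level lesions (mutations, copy
    number, structural variants), and NMF consensus clustering with cophenetic
    model selection and Fisher-exact marker discovery. Includes a synthetic
    cohort generator emulating the statistical structure of FL genomes so the
    whole pipeline is testable without access to patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    mclust
Config/testthat/edition: 3
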