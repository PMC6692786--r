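Package: ProteoBuffer
Title: Interaction-Mediated Buffering of Gene Dosage in Cancer Proteomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies protein-level attenuation of gene copy-number
    changes from matched CNV, mRNA and protein tumour profiles, classifies
    genes into attenuation classes with a Gaussian mixture model, and
    discovers controlling-to-controlled protein pairs (and phosphosite
    modulators of them) with nested linear models compared by likelihood
    ratio tests. Includes solvent-accessibility based extraction of
    protein-protein interface residues from PDB structures, validation of
    discovered pairs on normal-tissue expression panels, stratification of
    cis-eQTL GWAS-tagging fractions by attenuation class, and a synthetic
    multi-omics cohort generator with full ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    mclust,
    limma,
    edgeR,
    igraph,
    bio3d,
    jsonlite
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
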