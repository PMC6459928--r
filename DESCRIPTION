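Package: mrith
Title: Multi-Region Intra-Tumor Heterogeneity Analysis for Exome and TCR
    Repertoire Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-region tumor sequencing studies:
    numeric post-calling filters for somatic SNVs and indels, hypermutator
    flagging, germline homologous-recombination gene filters and driver
    annotation; cancer cell fraction estimation with clonal/subclonal
    classification and LOH calls; per-patient maximum-parsimony phylogenies
    from binary mutation presence tables with trunk/shared/private timing,
    clone intermixing detection and metastatic seeding classification;
    96-channel mutational spectrum construction and non-negative
    least-squares deconvolution against a 30-signature catalog, including
    trunk-versus-branch signature dynamics and signature-3 based BRCA1/2
    prediction; detection of mirrored subclonal allelic imbalance from
    per-SNP B-allele fractions; fitting of the neutral tumor growth model
    M(f) = (mu/beta)(1/f - f/f_max) with a purity-corrected variant; and
    T-cell receptor repertoire diversity, overlap and distance metrics with
    neighbor-joining trees. A synthetic multi-region cohort generator with
    known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate: 
    'mrith-package.R'
    'classes.R'
    'io.R'
    'ccf.R'
    'channels.R'
    'filters.R'
    'msai.R'
    'neutral.R'
    'tree-utils.R'
    'phylogeny.R'
    'tcr.R'
    'signatures.R'
    'pipeline.R'
    'simulate.R'
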