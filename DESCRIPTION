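Package: methyldup
Title: Genic DNA Methylation and Duplicate Gene Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Comparative-epigenomic analysis of duplicate gene evolution in
    plant genomes. Classifies genes by genic DNA methylation (gene-body
    methylated, TE-like methylated, unmethylated) from per-cytosine
    bisulfite calls using per-context binomial enrichment tests with
    Benjamini-Hochberg correction; classifies paralog pairs by duplication
    mechanism (whole-genome, tandem, proximal, translocated, dispersed)
    via collinear-block detection; categorizes orthogroups by phylogenetic
    breadth and copy number; estimates Ka, Ks and Ka/Ks with the
    Nei-Gojobori method; computes the tissue-specificity index tau and
    per-pair expression divergence; and provides the shared statistical
    layer (Fisher enrichment scans, two-proportion contrasts, sliding
    genomic windows, transposable-element association, presence-absence
    calling, population epiallele frequencies). A synthetic-data module
    generates complete toy datasets with known ground truth so every
    pipeline stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
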