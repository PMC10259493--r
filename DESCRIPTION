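Package: uorfquant
Title: Quantifying Upstream ORF Regulation from Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for massively parallel reporter assays of upstream
    open reading frame (uORF) regulation in yeast. Estimates per-construct reporter
    expression from binned sort-seq (FACS) sequencing counts, quantifies uORF effects
    from paired wildtype/start-codon-mutant constructs, decomposes repression into
    translational and nonsense-mediated-decay (NMD) components using paired
    wildtype/upf1-delta measurements, quantifies ribosome-loading effects from
    polysome-fraction sequencing, extracts uORF sequence and position features
    (Kozak context, folding energy, codon adaptation, peptide properties,
    conservation), and models uORF activity by elastic-net regression. Includes a
    synthetic-library simulator with planted ground truth so every stage is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    seqinr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
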