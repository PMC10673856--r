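Package: editscan
Title: CRISPR/Cas9 Editing Analysis for Nodule-Specific Cysteine-Rich Peptide Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for CRISPR/Cas9 editing studies of the Medicago
    truncatula NCR (nodule-specific cysteine-rich) peptide gene family:
    candidate-gene selection by conserved-cysteine motif, isoelectric point,
    charge class and nodule-zone expression filters; SpCas9 guide-site
    enumeration with 5'-base and cut-placement constraints and off-target
    mismatch search; per-nodule amplicon genotyping with allele-composition
    classification, editing-efficiency summaries and protein-consequence
    prediction; and TIDE-style decomposition of mixed Sanger chromatograms
    into an indel-size spectrum by non-negative least squares. Ships
    simulators for every input (peptide families, zone-wise expression
    tables, mixed-allele amplicon read sets, chromatogram traces) with
    recorded ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    pracma,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
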