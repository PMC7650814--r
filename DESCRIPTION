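Package: capstax
Title: Taxon-Diagnostic SNPs and CAPS Markers from Annotated Organelle Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies single-nucleotide polymorphisms that are diagnostic for a
    taxon (genus, family or order) from per-gene multiple alignments of annotated
    organelle genomes, and turns them into CAPS (cleaved amplified polymorphic
    site) markers by screening restriction enzymes with IUPAC-ambiguous
    recognition sites and Type IIS cut geometry, selecting short amplicons with
    conserved primer windows, and simulating PCR and restriction digestion.
    Includes supporting organelle-genome characterization: interspersed
    (nontandem) repeat detection by genome self-comparison, detection of
    chloroplast-like insertions, shared gene-order (synteny) clusters, and an
    open-reading-frame scan.  A seeded simulator emits annotated GenBank files
    for a toy taxonomy with planted diagnostic SNPs, enzyme sites, repeats and
    plastid-like insertions so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
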