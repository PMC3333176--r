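Package: rrnabin
Title: Taxonomic Binning of 16S rRNA Reads via SILVA-to-NCBI Accession Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Standalone toolkit for taxonomic analysis of 16S rRNA amplicon
    reads aligned against the SILVA ribosomal RNA database. Builds a
    SILVA-accession to NCBI-taxon-ID mapping file by name matching against
    the NCBI taxonomy dump (scientific names, synonyms, equivalent names and
    misspellings), with blocked-keyword handling ('uncultured',
    'unidentified', 'metagenome', 'environmental samples'), taxonomic-path
    climbing and capitalization retry. Assigns reads from BLASTN tabular
    output to NCBI taxa using accession lookup and lowest-common-ancestor
    binning under Min Score, Top Percent and Min Support thresholds, and
    compares the resulting taxonomic profiles across samples and external
    genus-level classifiers. Includes seeded generators for synthetic
    taxonomy dumps, SILVA exports and BLAST tables so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
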