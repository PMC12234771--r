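Package: camscan
Title: Comparative Variant Scanning, Codon Usage and Codon Aversion Analysis for Two Bacterial Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative pipeline for two closely related bacterial lineages
    represented by aligned single-copy ortholog coding sequences. Calls SNPs and
    INDELs against a lineage consensus reference and classifies them (transition
    versus transversion; small versus large, frame-preserving or not), computes
    per-category INDEL identity and divergence statistics, profiles codon usage
    (RSCU, effective number of codons, parity-rule-2 third-position biases,
    significantly variable codons, stop-codon preference) with F-test-then-t-test
    group comparisons, and extracts codon aversion motifs from which a strain
    identification decision map is built. Includes a two-clade coding-sequence
    evolver with a fully recorded event log (planted substitutions, INDELs and
    codon-aversion differences) so every scanner and statistic can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
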