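Package: uorfkit
Title: Upstream ORF Annotation, CRISPR Edit-Outcome Prediction, and Guide
    Design for 5' Leader Engineering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for engineering upstream open reading frames (uORFs) in
    plant 5' leader sequences. Scans a leader for upstream ATGs, extends each
    to its stop codon and classifies uORFs into the three positional types
    (non-overlapping, out-of-frame overlapping, and N-terminal extension).
    Applies CRISPR-style indel and substitution alleles to a reference and
    reports how the uORF landscape changes; enumerates and ranks SpCas9
    protospacers by cut-site proximity to uATGs; genotypes edited lines from
    cloned amplicon sequences via global alignment and variant calling, with
    zygosity classification and cohort editing statistics; and computes
    2^-ddCt relative expression, dual-luciferase translational efficiency
    ratios, total-tanshinone fold changes, and two-sample t tests. A
    constraint-based synthetic-data generator plants uORFs of specified
    types and lengths under a no-stray-ATG rejection sampler so every stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
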