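Package: cas9enrich
Title: Simulation and Quantification for Cas9-Based Amplification-Free Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for PCR-free, Cas9-targeted long-read metabarcoding studies.
    Scans genomes for PAM-adjacent protospacer matches with bounded mismatches and
    reports off-target sites, performs in-silico Cas9 digestion with asymmetric
    end-protection bookkeeping, samples sequencing libraries with an off-target
    background component, emits nanopore-like error-bearing reads with a truth
    table, assigns reads to marker references, computes fold-enrichment of a
    target region, copy-number-corrected expected community compositions,
    stranded coverage and read-length profiles, observed relative abundances with
    rank aggregation, and Lin's concordance correlation coefficient. Also
    implements idealized kinetic models contrasting PCR amplification bias with
    Cas9 enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
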