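Package: editomekit
Title: Quantification and ADAR-Specificity Classification of A-to-I RNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying adenosine-to-inosine (A-to-I) RNA editing from
    per-site pileup base counts in multi-genotype RNA-seq designs. Computes
    replicate-pooled per-genotype editing rates with coverage and minimum-rate
    filters, two-proportion z statistics for differential editing between
    genotypes, classification of sites as ADAR1/ADAR2 shared or enzyme-specific
    (including cross-enzyme inhibition patterns), sliding-window detection of
    hyperedited regions, gene-part and SINE-repeat annotation, and nucleotide
    sequence-context matrices around edited adenosines. Includes a fully
    deterministic synthetic-data generator that emulates a five-genotype,
    three-replicate brain RNA-seq editing study with known ground truth for
    validating the complete pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
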