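Package: hicdci
Title: Differential Chromatin Interaction Profiles and Transcriptional
    Regulator Inference from Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares intra-chromosomal Hi-C contact maps between two
    biological conditions to produce a genome-wide differential chromatin
    interaction (DCI) profile, using distance-decay normalization, paired
    t-tests over flanking contact score arrays and Fisher's combined
    probability.  The binned profile is projected onto a catalog of candidate
    cis-regulatory elements and screened against a compendium of
    transcriptional regulator binding profiles by AUROC, with per-regulator
    rank aggregation under the Irwin-Hall distribution, yielding ranked lists
    of regulators associated with increased or decreased chromatin
    interactions.  Reads HiC-Pro triplet matrices, cooler files and Juicer
    .hic files, and ships a synthetic-data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    IRanges,
    rhdf5,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
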