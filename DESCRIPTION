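Package: cnarray
Title: Integer Copy-Number Calling from Array Intensity Data with
    Contamination and Ploidy Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates integer DNA copy numbers from SNP-array and
    oligonucleotide-array intensity data.  Combines quartet-level
    perfect-match/mismatch intensities into one normalized signal per SNP
    using a reference panel (amplicon-size normalization, allele-specific
    rescaling, inverse-variance quartet weighting), maps signal to copy
    number through a calibrated response curve, jointly estimates benign
    tissue contamination (alpha) and a genome-size normalization factor
    (beta) from histogram peaks of the smoothed signal, and decodes the
    most likely integer copy-number path per chromosome with a hidden
    Markov model, iterating until the sample model converges.  Includes a
    seeded simulator for reference panels, trios, aneuploid genomes, and
    tumor-normal admixtures so that every stage can be tested without
    real arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
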