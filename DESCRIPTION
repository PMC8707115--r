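Package: attinakaryo
Title: Karyomorphometry and Karyotype Evolution of Fungus-Farming Ants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative cytogenetics of the fungus-farming ants
    (Formicidae: Myrmicinae: Attini: Attina). Computes karyomorphometric
    statistics (total, long-arm and short-arm lengths, arm ratio, relative
    length) from per-metaphase chromosome measurements, classifies chromosome
    morphology from the arm ratio, and assembles karyotype summaries (diploid
    number, karyotype formula, fundamental number, karyotype length).
    Parses, validates and summarizes compiled cytogenetic record tables
    (chromosome counts, karyotype formulas, C-band heterochromatin position
    codes, 1C genome sizes), maps haploid chromosome number and genome size
    onto a time-calibrated phylogeny to detect clade-level karyotype stasis,
    and simulates noisy metaphase spreads, fission/fusion chromosome-number
    evolution and Brownian genome-size evolution for testing and exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
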