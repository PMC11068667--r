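Package: karyodrive
Title: Transmission Distortion Scans for Pooled Sequencing of Hybrid
    Butterfly Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect transmission ratio distortion at chromosome
    fusion/fission rearrangements from pooled whole-genome resequencing of
    F2 hybrid offspring. Includes a forward simulator of achiasmatic female
    meiosis with a holocentromere-strength drive parameter for
    heterokaryotypic trivalents, pooled read-count generation with
    orientation-specific reference bias, dual-reference allele frequency
    estimation with a likelihood-ratio polymorphism filter, exact two-sided
    binomial tests with Clopper-Pearson intervals per rearrangement class,
    and a coverage-based aneuploidy scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
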