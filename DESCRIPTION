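Package: kinfuse
Title: Kinase Fusion Discovery from RNA-Seq Chimeric Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calls gene fusions from chimeric-alignment evidence (discordant
    read pairs and junction-spanning split reads), applies per-sample filters
    (tiered read support, 5'->3' strand concordance, partner homology) and
    cohort-level filters (improbable-frequency flags, panel of normals,
    cross-cohort recurrence), and annotates recurrent kinase fusions with
    junction class, predicted reading frame, kinase-domain conservation,
    coiled-coil dimerization motifs and artifact flags, yielding a
    driver/passenger/artifact verdict per fusion. Includes a synthetic-cohort
    generator that emits every input the pipeline consumes, with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
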