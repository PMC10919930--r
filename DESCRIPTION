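Package: whalescan
Title: Alignment-Column Trait Association Scans and Windowed
    Population-Genomic Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting alignment columns whose alleles associate
    with a quantitative species trait (log adult body mass) via per-column
    partial F tests with permutation-based false discovery rate estimation,
    and for classifying significant columns into clade-sharing site types.
    Also provides the windowed population-genomic stage used alongside such
    scans: depth filtering of genotype calls, windowed heterozygosity, runs
    of homozygosity with Froh and length bins, pseudodiploid track
    construction, and PSMC input export, together with a synthetic-data
    generator so every stage can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    seqinr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
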