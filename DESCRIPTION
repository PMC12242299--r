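Package: sedadna
Title: Sedimentary Ancient DNA Metabarcoding Inference Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring past biodiversity from replicated sedimentary
    ancient DNA (sedaDNA) metabarcoding experiments. Implements the
    quality-control cascade for amplicon sequence variant (ASV) tables
    (orientation merging, post-clustering error curation, replicate-support
    and negative-control filtering, amplicon length filtering, lane
    combination), lowest-common-ancestor and consensus taxonomy assignment
    over alignment hit tables, PCR-replicate detection-proportion statistics,
    a Monte-Carlo piecewise-linear age-depth model for dated sediment
    horizons, regression of detection proportions against palaeoclimate
    proxies with low-pass proxy smoothing, weighted centennial
    zooarchaeological marine-resource proportions, and a synthetic
    sediment-core generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    broom,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
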