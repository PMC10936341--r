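Package: pwat
Title: Weighted Multi-Form Welfare Assessment Scoring for Research Primate Facilities
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scoring and benchmarking engine for a weighted welfare-descriptor
    instrument used to assess behavioural management programmes for research
    macaques. Implements the instrument registry (133 weighted descriptors in
    six welfare categories across room-level, site-level and culture-of-care
    interview forms), prevalence-band answer mapping, NA-aware percentage
    scoring with bonus items and a capped single-housing penalty, multi-room
    and multi-site aggregation, annual benchmarking, audit sampling plans,
    gap reporting, and a synthetic campaign simulator with known ground-truth
    facility quality for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    jsonlite,
    readr,
    stringr,
    generics,
    ggplot2,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
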