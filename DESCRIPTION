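Package: fieldcensus
Title: Estimating the Size of Biomedical Research Fields from Unique Author Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bibliometric estimation of the size of biomedical research
    fields. Parses PubMed exchange formats (MEDLINE tagged text and PubMed
    XML), applies an eligibility filter keeping records with a publication
    date and fully named authors, and measures field size as the number of
    unique (first, last) author names per calendar year. Fits and compares
    linear and exponential growth models of field size over time, adjusts
    funding series for inflation with a consumer price index, computes
    funding per author, and correlates workforce size with disease case
    burden. Includes a synthetic publication-corpus generator with known
    ground truth for validating the census and model-fitting machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
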