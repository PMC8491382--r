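Package: ddaminer
Title: Disease-Disease Association Mining from Literature Co-Mentions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for building disease-disease association (DDA)
    networks from biomedical abstracts. Reads and writes PubTator-format
    corpora, builds disease concept lexicons from MeSH-style descriptor
    XML or term tables, recognizes disease mentions with a deterministic
    dictionary longest-match tagger, normalizes mentions to MeSH/OMIM
    concept identifiers with an explicit unknown sink, scores predictions
    against gold annotations with span-level and concept-level
    precision/recall/F1, aggregates document-level co-mentions into
    ranked DDA networks, derives gene-overlap DDAs from disease-gene
    tables via the Jaccard index with a shared-gene threshold, and
    quantifies agreement between two DDA networks. A synthetic-fixture
    generator produces corpora, lexicons, corrupted predictions and gene
    tables with known ground truth for calibration and testing.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
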