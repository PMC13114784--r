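Package: insertarch
Title: Detection and Analysis of Protein Domain Insertion Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects A1-B-A2 domain insertion events in multidomain proteins
    from ECOD-style hierarchical domain assignments, classifies family-level
    architectural roles (host-consistent, insertion-consistent, versatile),
    and computes the size, position, partnership, enrichment, and
    N/C-termini geometry statistics that characterise insertion
    architectures. Includes a synthetic architecture generator with ground
    truth for validating every pipeline stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
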