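Package: roar
Title: Region of Attainable Redaction Analysis for Dichotomous Outcome Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how much hypothetical data redaction in the
    experimental and/or control arm of a dichotomous outcome trial would be
    needed to turn an ostensibly significant chi-squared result into a null
    one. Constructs the Region of Attainable Redaction (ROAR), a bounded
    cubic region in redaction space, solves for the minimal-length FOCK
    (Fewest Observations/Censored Knowledge) redaction vector by Lagrange
    multipliers, and reports per-arm and total redaction tolerances.
    Includes a confounding-gated extension to pooled meta-analysis tables
    via crude and Cochran-Mantel-Haenszel risk ratios, brute-force oracles
    for validation, a seeded generator of significant tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
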