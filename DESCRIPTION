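Package: qboots
Title: Bootstrapped Q-Methodology Analysis with Alignment Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Q-methodology analysis of forced-distribution Q-sorts (correlation of
    respondents, principal-component extraction, varimax rotation, automatic
    flagging, statement z-scores and factor scores, distinguishing and consensus
    statements) together with a non-parametric bootstrap of the Q-sorts that
    corrects the factor alignment problem (axis reordering and reflection) against
    the full-sample target loadings. The bootstrap yields statement-specific and
    respondent-specific variability estimates: z-score standard errors and bias,
    loading standard errors, and flagging frequencies. Includes a synthetic Q-sort
    generator with known latent archetypes for parameter-recovery checks, CSV/JSON
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
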