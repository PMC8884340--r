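Package: bifluency
Title: Scoring and Analysis of Bilingual Verbal Fluency Tasks
Version: 0.1.0
Authors@R: person("BiFluency", "Maintainers", email = "maintainers@bifluency.org",
                  role = c("aut", "cre"))
Description: Condition-aware scoring of bilingual verbal fluency transcripts
    (category generation under no-switch, self-switch and forced-switch
    language conditions, and letter fluency), including phoneme-tolerant
    correctness rules, semantic and phonemic clustering and switching
    metrics, and fluency difference scores. Ships a synthetic bilingual
    cohort generator that emulates the group and condition structure of an
    aphasia versus healthy-bilingual study design, and a statistical
    battery: mixed repeated-measures ANOVA with partial eta squared,
    planned contrasts with false-discovery-rate adjustment, principal
    component analysis with varimax rotation and regression factor scores,
    and backward stepwise regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
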