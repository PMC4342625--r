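Package: steptailor
Title: Computer-Tailored Pedometer Step Advice and Cluster-Trial Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pedometer-based physical activity promotion research:
    a rule-based engine that generates computer-tailored step advice from a
    psychosocial diagnostic questionnaire (stage-of-change classification,
    weekly step-goal schedules toward 10,000 steps/day, determinant-matched
    feedback messages), quality control and averaging of daily pedometer
    logs, IPAQ short-form scoring in minutes/day, a synthetic cluster
    randomized trial generator with differential dropout, and the matching
    analysis pipeline (baseline comparisons, dropout analysis, cluster
    variance check, repeated-measures ANCOVA on change scores, guideline
    attainment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glue,
    tibble,
    dplyr,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
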