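Package: engagelca
Title: Engagement Patterns in Online Interventions via Latent Class Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for process evaluation of online behavioral interventions
    from timestamped feature-use logs. Converts raw event logs into categorical
    engagement indicators (consistency of use across 45-day intervals and
    quantity of use relative to the user median), discovers engagement
    patterns and demographic/BMI subgroups with a latent class analysis
    engine (EM with multiple random starts; G-squared, AIC and BIC model
    selection; posterior classification; label alignment), and tests
    class-by-subgroup associations with Pearson chi-square tests. Includes a
    synthetic event-log generator with known class structure so every stage
    of the pipeline can be exercised and validated without access to
    participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
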