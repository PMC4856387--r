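Package: stereomet
Title: Behavioural Metrics for Stereotypy, Perseveration and Cognitive Bias in Mice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the behavioural phenotyping of laboratory mice:
    a closed-loop controller for the adaptive two-choice guessing task
    (bait probability tracking the subject's recent side bias), Markov-chain
    scoring of recurrent perseveration (sum chi-square over third-order
    contexts, logit-transformed P), tetragram repetition/alternation analysis,
    cognitive (judgement) bias scores from radial-maze arm-occupancy logs, and
    one-zero interval sampling of home-cage ethogram streams with stereotypic
    bout classification. Includes seeded synthetic-data generators (choice
    agents, maze visit logs, ethogram event streams) so every analysis stage
    has a parameter-recovery test surface, plus TSV/JSON readers and writers
    and a pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
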