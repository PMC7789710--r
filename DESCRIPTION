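Package: lungmatch
Title: Revealed-Preference Analysis of U.S. Lung Allocation Match Runs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the classification-based U.S. lung
    allocation policy ranks transplant candidates and how closely that
    policy can be approximated by a continuous, points-based composite
    score.  Includes a deterministic match-run ranking engine for the
    zone/age/ABO classification grid, a seeded synthetic cohort and
    match-run generator, maximum-likelihood estimation of rank-ordered
    (exploded) logit models on ranked candidate lists, composite-score
    construction with attribute-importance and nautical-mile exchange-rate
    summaries, and rank-agreement evaluation (Kendall's tau-b, Spearman)
    between policy ranks and score-based ranks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
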