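Package: crowdaffect
Title: Reliability and Quality of Crowdsourced Affect Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing whether crowdsourcing yields reliable and
    high-quality emotion labels for pictures rated on the Self-Assessment
    Manikin (SAM) valence, arousal and dominance scales. Provides two-way
    random-effects intraclass correlations under both the consistency and
    absolute-agreement definitions from an exact ANOVA mean-squares
    decomposition, Hartigan's dip statistic with Monte-Carlo calibration for
    per-picture modality calls, rater-subsampling simulations that estimate
    the minimum number of ratings per picture needed to reach a target
    reliability band, binarized opinion-transfer analysis across polarizing
    pictures, comparison of aggregated crowd labels against gold (normative)
    labels, and a synthetic rating generator that emulates the statistical
    structure of crowdsourced SAM annotation campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
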