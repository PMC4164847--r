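Package: fahp
Title: Improved Fuzzy Analytic Hierarchy Process for Sustainability Evaluation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-criteria evaluation engine built on an improved fuzzy
    analytic hierarchy process (FAHP) with a three-scale {0, 0.5, 1}
    complementary judgment calculus. Expert pairwise scores are aggregated
    into fuzzy complementary judgment matrices, transformed into additively
    consistent matrices, converted to positive reciprocal matrices, and
    refined into priority vectors by power iteration. Local priorities are
    synthesized down a multi-level indicator hierarchy into composite leaf
    weights, raw indicator values are standardized by threshold (min-max)
    and fractional scaling, and alternatives are ranked by a linear-weighted
    comprehensive score. Includes calculators for common ecological benefit
    indicators (Simpson diversity, Shannon stability, and monetary valuation
    formulas for water, soil, and air services), synthetic fixture
    generators for hierarchies and expert panels, and a bundled forest
    harvesting case study comparing light cableway skidding with
    road-skidding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
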