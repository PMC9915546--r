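Package: vegrisk
Title: Trace-Metal Contamination, Transfer and Probabilistic Ingestion Risk
    in Paired Soil-Vegetable Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assessment toolkit for trace metals (Cd, Cr, Cu, Pb, V, Zn) in
    paired agricultural soil and leafy-vegetable samples. Computes
    geo-accumulation indices with contamination classes, guideline-exceedance
    screening, soil-to-vegetable bioaccumulation factors and their
    correlations with soil physicochemical properties, source-apportionment
    statistics (Pearson correlation matrices and principal component
    analysis), and deterministic plus Monte Carlo non-carcinogenic health
    risk (chronic daily intake, hazard quotient and hazard index) for adult
    and child receptors with log-normal content distributions. Includes a
    calibrated synthetic paired-dataset generator with planted two-source
    structure and soil-property effects on transfer, so every stage of the
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
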