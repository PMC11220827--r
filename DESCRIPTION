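Package: ngra
Title: Exposure-Led Next-Generation Risk Assessment with Read-Across and
    PBPK Reverse Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exposure-led next-generation risk assessment (NGRA) of
    cosmetic ingredients by read-across. Implements a configurable
    perfusion-limited physiologically based pharmacokinetic (PBPK) model for
    oral and dermal repeated dosing with Monte Carlo population variability
    and reverse dosimetry; point-of-departure derivation from multi-assay in
    vitro panels including pathway-level aggregation of transcriptomic
    benchmark doses and a safety-factor chain; bioactivity-exposure ratios and
    traditional margins of safety; analogue-similarity (read-across) evidence
    assembly; in vitro biokinetics metrics; and a synthetic data generator so
    the whole pipeline is testable without external data. Ships a worked
    isoflavone (daidzein/genistein) case study as packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
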