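Package: heparcomp
Title: Comparison of Low Molecular Weight Heparin Component Tables from
    Top-Down LC-MS
Version: 0.1.0
Authors@R:
    person("heparcomp", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for comparing replicate or batch component tables from
    top-down LC-MS compositional analysis of low-molecular-weight heparins
    such as enoxaparin.  Reads tab-delimited match tables (compound key,
    score, total ion volume), removes noise rows with empty compound keys,
    screens false positives by requiring a composition to be present in
    every sample ("all-presence" filtering), merges ammonium-adduct
    variants of each composition (maximum score, summed volume), and
    reports relative abundances normalized to the ten most abundant
    components.  Also enumerates the enoxaparin intact-chain composition
    hypothesis under standard constraints, matches deconvoluted masses
    within a ppm tolerance, evaluates false-positive rates against manual
    truth annotations, and generates synthetic replicate tables with
    planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
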