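Package: llspin
Title: Long-Lived Spin States of CH2 Chains: SLIC Simulation and
    Paramagnetic Relaxivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coherent density-operator simulation of spin-lock induced
    crossing (SLIC) and polychromatic SLIC experiments on chains of
    geminal proton pairs (CH2 groups), including construction of the
    complete basis of long-lived subset-product operators, ideal T00
    filtering, trace-projection decomposition of excited long-lived
    states, and optimization of full-cycle magnetization-to-LLS
    conversion efficiency.  A companion relaxometry pipeline fits
    mono-exponential signal decays, regresses relaxation rate constants
    against paramagnetic radical concentration to obtain relaxivities,
    and summarizes relaxivity ratios for long-lived versus longitudinal
    order.  A seeded generator produces synthetic TEMPOL titration
    datasets for end-to-end validation of the fitting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
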