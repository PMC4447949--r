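Package: etsface
Title: Structural and Biochemical Analysis of Ets Domain-DNA Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein-DNA interfaces of winged
    helix-turn-helix (Ets domain) transcription factor complexes: contact
    detection and classification (hydrogen bonds, salt bridges, van der Waals),
    Shrake-Rupley solvent-accessible surface area and buried interface area,
    DNA base-pair detection, bend angle and groove-width profiles against an
    idealized B-form reference, bridging-water network identification with
    exhaustive hydrogen donor/acceptor assignment, in-silico 5-methylcytosine
    and phosphoserine modification with steric clash scanning, normalized
    B-factor order-disorder profiles, pairwise sequence identity, and Hill
    model equilibrium binding (EMSA) isotherm simulation and fitting with
    fold-inhibition statistics. Includes a synthetic-structure generator
    (fiber-model B-DNA, planted-interaction complexes, planted water networks)
    so every analysis stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
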