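Package: qrsite
Title: Quantum-Refinement-Style Evaluation of Metal Sites in Cryo-EM Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to re-evaluate the chemical interpretation of metal sites in
    cryo-EM structures by combining a real-space map-fit target with an energy
    term for a small carved site (quantum-refinement-style), scoring candidate
    interpretations by strain energy and real-space correlation, selecting the
    map weight by a scan rule, and ranking alternatives such as metal-versus-water
    or dinuclear-versus-mononuclear models. Includes a synthetic-data generator
    (toy copper sites, rendered noisy density) and a built-in surrogate site-energy
    engine so the whole pipeline runs without an external quantum-chemistry code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
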