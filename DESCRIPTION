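Package: ogtrace
Title: Optimal Growth Temperature Inference from Elongation Factor
    GDP-Binding Thermal Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers optimal growth temperatures (OGT) of extant and
    ancestral prokaryotes from the temperature dependence of GDP binding
    by translation elongation factors (EF-1A/EF-Tu). Fits replicate
    fluorescence-versus-temperature profiles with a five-parameter skewed
    Gaussian-like peak model, builds bootstrap percentile confidence
    intervals for the peak temperature, determines thermal stability
    ranges from ThermoFluor melt curves, constructs consensus ancestral
    sequences from multiple reconstruction methods with per-site
    posterior probabilities, classifies thermal lifestyles, and maps OGT
    estimates onto rooted phylogenies. Includes seeded generators for
    every input so the full pipeline is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    ape,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
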