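Package: phytoextract
Title: Factorial Optimization, Kinetics and Thermodynamics of
    Bioactive-Compound Extraction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the solid-liquid extraction of bioactive compounds from
    plant material and the biological activity of the resulting extracts.
    Provides a 2^k full factorial design analysis of extraction conditions
    (coded first-order polynomial with all interactions, effect ANOVA,
    percentage contributions, model reduction and prediction), two-parameter
    extraction kinetics (unsteady-state diffusion and Ponomarev models fitted
    through their linearized forms and compared by R-squared and relative
    root-mean-square deviation), Arrhenius activation energies and
    transition-state thermodynamics (activation enthalpy, entropy and Gibbs
    energy) of the slow extraction stage, and bioassay summarization (IC50
    interpolation from dose-response curves, MIC reduction of broth
    microdilution series, and Pearson correlation of activity panels).
    A synthetic-data generator emulates every input with explicit noise
    models so that the whole chain is testable end to end, and reference
    datasets from a maceration study of Erica carnea L. are bundled.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
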