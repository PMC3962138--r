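Package: nadq
Title: Targeted Isotope-Dilution LC-MS/MS Quantification of the NAD+ Metabolome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for targeted, quantitative measurement of the
    NAD+ metabolome by selected-reaction-monitoring (SRM) LC-MS/MS with
    stable-isotope-dilution internal standards. Turns per-transition
    chromatogram traces (real or simulated) into integrated peaks with
    signal-to-noise, fits standard curves over a nine-level concentration
    series with limit-of-quantification and linear-range determination,
    assigns pmol amounts to a uniformly 13C-labelled yeast-extract internal
    standard lot (plus 18O-labelled nicotinamide and nicotinamide riboside),
    quantifies analytes by light/heavy peak-area ratios with surrogate
    correction factors, converts amounts to intracellular molar
    concentrations via explicit extraction-volume bookkeeping, and computes
    method/system precision and crosstalk QC. Includes a synthetic SRM run
    generator with shared-ionization-suppression, on-source-fragmentation and
    isotopologue-bleed phenomena for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
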