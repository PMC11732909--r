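Package: xenotherm
Title: Thermophysiology of Extinct Ground Sloths from Clumped Isotopes and
    Biophysical Heat-Balance Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An inference chain for reconstructing the thermophysiology of
    extinct xenarthrans (ground sloths). Reduces clumped-isotope (D47)
    replicate measurements to core body temperature estimates with
    standards-based correction and formation-water d18O estimation; screens
    fossil samples for diagenetic alteration with a PAAS-normalised
    rare-earth-element index and the carbonate-phosphate d18O offset;
    computes basal and field metabolic rates from allometric scaling laws;
    solves a steady-state heat balance for a fur-insulated endotherm to
    locate thermoneutral zones; drives the animal model with reconstructed
    hourly microclimates to produce daily energy budgets, thermal stress
    classes, activity hours and forage intake; and generates synthetic
    datasets with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
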