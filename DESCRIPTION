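Package: readerbind
Title: Biophysical Characterization of Histone-Reader Domain Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for the biophysical characterization of
    histone-tail reader domains such as the ASHH2 CW domain binding
    methylated H3K4 peptides. Fits the single-site ("independent") binding
    model to isothermal titration calorimetry (ITC) injection heats and
    derives Gibbs energy, enthalpy and entropy decompositions; fits
    four-parameter logistic melting transitions to intrinsic tryptophan
    fluorescence intensity ratios (I328/I352) and extracts melting
    temperatures with a sigmoidality gate; computes amide chemical-shift
    perturbations and fingerprint-shift fractions from 1H-15N peak lists;
    computes heteronuclear NOE ratios and mono-exponential relaxation
    times; and measures binding-pocket tryptophan ring-plane angles from
    PDB coordinates. Includes deterministic synthetic-data generators for
    every input class so the whole pipeline is testable without
    instrument output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    bio3d,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
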