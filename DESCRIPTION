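Package: hfepr
Title: High-Field EPR, ENDOR and ELDOR-NMR Analysis of Mn(II) Metalloprotein Active Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing high-spin Mn(II) (S = 5/2) active sites
    in metalloproteins from high-field magnetic-resonance data. Simulates
    powder field-swept echo EPR spectra from zero-field-splitting parameters
    and inverts labelled turning points back to D and E; computes
    orientation-selective effective hyperfine couplings from tensor
    projections; generates and fits single- and multiple-quantum ENDOR and
    ELDOR-detected NMR spectra as Gaussian component mixtures; inverts
    point-dipole hyperfine couplings to metal-proton distances; and orients
    the zero-field tensor in the molecular frame by brute-force Euler-angle
    search against externally supplied hyperfine tensor sets. Includes a
    synthetic-data generator producing toy trigonal-bipyramidal
    Mn(II)-His3-Asp-H2O sites for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
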