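Package: scivr
Title: Semiclassical and Quasiclassical Vibrational Power Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-trajectory vibrational spectroscopy on analytic model
    potentials: quasiclassical trajectory (QCT) power spectra from
    Fourier-transformed normal-mode momenta, time-averaged semiclassical
    initial value representation (TA SCIVR) spectra with the Herman-Kluk
    prefactor phase, multiple-coherent (MC) reference states, and
    divide-and-conquer (DC SCIVR) subspace projection. Includes symplectic
    propagation with monodromy-matrix and classical-action accumulation,
    Hessian-based normal-mode analysis, sinc-DVR quantum oracles for one- and
    two-dimensional surfaces, and a peak-assignment workflow (peak picking,
    FWHM, scaled-harmonic comparison, mean absolute errors, spectral-signature
    classification) for hydrogen-bonded tautomer discrimination such as the
    guanine-cytosine base pair.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
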