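Package: vcdspec
Title: Ensemble-Averaged IR and VCD Spectra for Flexible Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing toolkit for conformer-ensemble vibrational
    spectroscopy of flexible (cyclic) oligopeptides and similar molecules.
    Takes per-conformer quantum-chemistry results (geometries, energies,
    harmonic frequencies with dipole and rotational strengths) and performs
    conformer deduplication by energy, Kabsch-superposition RMSD and
    rotational constants; energy-window selection; Boltzmann weighting;
    Lorentzian band broadening into ensemble-averaged IR and VCD spectra;
    and quantitative spectral comparison via a normalized overlap integral
    with joint IR+VCD frequency-scaling optimization. Includes a synthetic
    fixture generator so every stage is testable without external software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    stats,
    utils,
    jsonlite,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
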