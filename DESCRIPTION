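Package: im30unfold
Title: Three-State Analysis of Urea-Induced IM30 Oligomer Disassembly and
    Monomer Unfolding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing chemical denaturation of the oligomeric
    ESCRT-III superfamily protein IM30 (Vipp1). Extracts scalar probes
    (fluorescence intensity at 335 nm, emission maximum, Rayleigh
    scattering at 300 nm, ellipticity at 208/222 nm and their ratio) from
    wavelength-resolved spectra, assembles and normalizes denaturation
    series, and globally fits a three-state oligomer/intermediate/unfolded
    equilibrium in which the native-oligomer fraction is pinned to the
    normalized static-light-scattering signal and the intermediate-unfolded
    step follows the linear extrapolation model. Also provides the
    dihedral-window helicity statistics used for coarse-grained
    trajectories, a cooperative helix-coil stand-in model with an exact
    transfer-matrix solution and a Metropolis sampler, Shrake-Rupley
    solvent-accessible surface areas for tryptophan indole rings in
    different structural contexts, and a seeded synthetic-data generator
    that emulates the statistical structure of the spectroscopic
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
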