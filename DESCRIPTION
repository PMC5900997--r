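Package: svisim
Title: Virtual Oxygen-Enhanced MRI Specific Ventilation Imaging Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward physiological simulator of pulmonary ventilation,
    perfusion and oxygen exchange on a synthetic anatomically structured
    lung, together with the magnetic-resonance side of specific
    ventilation imaging (SVI): a 220-breath alternating air/oxygen
    protocol, voxelization of tissue and pulmonary-venous oxygen signal
    onto an imaging grid, response-curve based specific-ventilation
    inference by Spearman template matching, and in-plane misalignment
    simulation. Includes a volume-filling airway tree generator with
    matched arterial and venous trees, a Poiseuille flow network solver
    with compliant acini, a gravitational steady-state perfusion model
    with pressure-dependent vessel diameters, operator-split 1D
    advection-diffusion gas transport, and alveolar-capillary gas
    exchange with oxyhemoglobin buffering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite,
    igraph,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve
Config/testthat/edition: 3
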