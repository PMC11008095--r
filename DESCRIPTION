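Package: pcmresp
Title: Electrostatic Parametrization of Polarizable Gaussian Multipole
    Models in Continuum Solvents
Version: 0.1.0
Authors@R:
    person("pcmresp", "developers", email = "pcmresp@example.org",
           role = c("aut", "cre"))
Description: Restrained, constrained least-squares derivation of atomic
    monopoles and permanent covalent-bond dipoles for fixed-charge (RESP)
    and polarizable Gaussian multipole (pGM-ind, pGM-perm) electrostatic
    models, fitted against quantum-mechanical electrostatic potentials
    computed in dielectric media.  Polarizable-continuum surface charges
    enter the induced-dipole equations as static sources, so parameters can
    be developed directly in solution and in dual-solvent combined fits.
    Includes fitting-quality and cross-solvent transferability metrics
    (RMSE/RRMSE transfer matrices, molecular dipole moments), text-format
    readers and writers for ESP datasets and parameter files, a synthetic
    forward-model data generator standing in for quantum-chemistry output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
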