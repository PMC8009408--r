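Package: colonyflow
Title: Repulsive-Expansion Dynamics of Growing Cell Colonies and Synthetic
    Gene-Circuit Patterning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained Lagrangian simulation of radially symmetric colony
    expansion driven by cell division ("repulsive expansion"): interior growth
    generates a radial velocity field that advects tracked positions, with a
    shared nutrient pool setting the final colony size. The growth layer is
    coupled to a synthetic patterning gene circuit (self-activating T7 RNA
    polymerase, quorum-sensing AHL as a well-mixed global signal, AHL-induced
    T7 lysozyme, T7-lysozyme complex inhibition) modulated by a
    position-dependent gene-expression capacity and feeding back on growth
    through metabolic burden. Includes ring/core pattern quantification,
    scale-invariance sweeps over habitat size, an independent Eulerian upwind
    reference solver for validation, YAML run configurations with packaged
    regime presets, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
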