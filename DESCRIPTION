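Package: anmflex
Title: Native Protein Flexibility from All-Atom Anisotropic Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds all-atom (heavy-atom) anisotropic elastic network models
    from protein crystal structures and computes two native-state flexibility
    observables from their normal modes: an overall protein spring constant
    obtained from the cumulative mode variance, and a directional spring
    constant along the axis joining the C-alpha atoms of a chosen residue
    pair, the axis stretched in single-molecule pulling experiments. Includes
    cutoff scans with connectivity diagnostics, cumulative-mode convergence
    profiles, deterministic synthetic structure generators with independent
    brute-force oracles for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: bio3d, jsonlite, stats, utils, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
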