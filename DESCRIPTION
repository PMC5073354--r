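Package: allopath
Title: Structural Dynamics of Direct and Allosteric Protease Inhibition
Version: 0.1.0
Authors@R: person("allopath", "maintainers", email = "maintainers@allopath.dev", role = c("aut", "cre"))
Description: Tools for dissecting direct (active-site) and indirect (exosite)
    inhibition of serine proteases from crystal structures and conformational
    ensembles. Implements fixed-column PDB input/output with multi-model
    ensembles, Kabsch superposition and RMSD, Shrake-Rupley solvent-accessible
    surface area and interface burial, geometric hydrogen-bond and salt-bridge
    detection, ligand-induced conformational-segment calling with a t-test
    classification rule, Calpha anisotropic elastic-network normal modes with
    ensemble projection and population-shift detection, mode-based dynamical
    cross-correlation matrices, decoy-based mutational local frustration
    networks with exosite-to-active-site path tracing, and ensemble steric
    clash screening of a grafted inhibitor. Ships seeded synthetic-structure
    generators so every stage is testable without downloading coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
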