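Package: bindmode
Title: Consensus Protein-Protein Binding-Mode Inference and Interface
    Analysis
Version: 0.1.0
Authors@R:
    person("bindmode", "developers", email = "bindmode@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring a consensus protein-protein binding mode
    from docked pose sets pooled across several docking engines: interface
    distance-restraint checking, Kabsch superposition onto a common
    receptor frame, heavy-atom RMSD clustering with Kelley-penalty
    selection of the cluster count, and centroid-pose extraction with
    per-engine contribution statistics.  Companion modules detect typed
    interface interactions (hydrogen bonds, salt bridges, pi-stacking,
    aromatic hydrogen bonds), compute contact occupancy, distance monitors,
    RMSD/RMSF and trajectory clustering over coordinate-frame series, and
    estimate a declared surrogate binding free energy with per-frame
    averaging, computational alanine scanning and hot-region grouping.
    Synthetic generators (toy complexes with planted contacts, multi-engine
    pose ensembles with a planted mode, jittered trajectories) make the
    full pipeline runnable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
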