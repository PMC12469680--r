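Package: allokit
Title: Allosteric Activation Analysis for Serpin Conformational Switches
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for quantifying allosteric activation of
    antithrombin and related serpins. Identifies allosteric-communication-network
    residues from pairs of conformer crystal structures via iterative trimmed
    Kabsch superposition and distal side-chain-carbon displacement scanning;
    fits pseudo-first-order protease-inhibition progress curves and
    stoichiometry titrations to obtain second-order association rate constants
    and activation metrics; performs double- and triple-mutant thermodynamic
    coupling analysis on rate tables; fits two-state van't Hoff thermal
    denaturation curves and fluorescence baselines and gains; and analyses
    molecular-dynamics trajectories by C-alpha principal component analysis and
    differential residue-residue correlation maps. Includes seeded synthetic
    data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
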