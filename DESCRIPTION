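Package: atriablock
Title: Multiscale Simulation of Potassium-Channel Block in Persistent
    Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Mechanistic toolkit for studying multichannel inward-rectifier
    block as an antiarrhythmic strategy in persistent atrial fibrillation.
    Implements the Courtemanche-Ramirez-Nattel human atrial myocyte model
    extended with the Kneller acetylcholine-activated inward rectifier and a
    persistent-AF ionic remodeling profile; steady-state Hill-type
    pharmacology of chloroquine block of IK1, IKACh and IKr with
    variable-slope concentration-response fitting; single-cell pacing and
    titration protocols (APD90, resting membrane potential); a 2D monodomain
    reaction-diffusion tissue solver with S1-S2 arrhythmia induction;
    pseudo-unipolar electrogram synthesis, conditioning, dominant-frequency
    analysis and morphology classification; and a voxel-based probe scan that
    estimates whether a docked ligand occludes an ion channel's permeation
    pathway. Deterministic synthetic-data generators make every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    minpack.lm,
    signal,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
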