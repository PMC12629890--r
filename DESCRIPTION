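Package: stncoalign
Title: Co-Alignment of Microelectrode Recordings with Imaging-Derived
    Subthalamic Nucleus Meshes
Version: 0.1.0
Authors@R:
    person("STN Coalign", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconciling intraoperative microelectrode recordings
    (MER) with a preoperative imaging-derived mesh of the subthalamic
    nucleus (STN) during deep brain stimulation surgery. Computes
    normalised root-mean-square (NRMS) features per recording depth,
    classifies depths as inside or outside the STN with a threshold rule
    or a small attention-based sequence encoder, and estimates the rigid
    shift of the electrode trajectories together with an isotropic scaling
    of the STN mesh that minimises disagreement between the
    electrophysiological labels and mesh inclusion, using Powell's
    derivative-free method under clinically motivated bounds. Includes a
    PCA statistical shape model over vertex-corresponded meshes, watertight
    triangle-mesh queries (inclusion, surface distance, scaling), mesh and
    table I/O (STL, PLY, legacy VTK, CSV), evaluation metrics (fraction of
    STN-labelled sites inside the mesh, lateral trajectory distance, Dice
    overlap via voxelisation), and a fully seeded synthetic-scene generator
    (Ben-gun electrode geometry, simulated MER signals, injected
    ground-truth shift and scale) for validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
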