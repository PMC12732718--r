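Package: lndfusion
Title: Fusion Analysis of Ionizable-Lipid Nanodroplets with Endosomal
    Membranes from Coarse-Grained Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for coarse-grained molecular-dynamics
    trajectories of lipid nanodroplet (LND) fusion with endosomal membrane
    bilayers. Implements the Henderson-Hasselbalch protonation design
    calculus for ionizable lipids (ALC-0315, D-Lin-MC3-DMA), fusion-onset
    detection from the signed distance between the nanodroplet and the
    proximal leaflet, leaflet/midplane classification of ionizable-lipid
    head groups (flip-flop quantification), head-group radial distribution
    functions, single-linkage maximum-cluster tracking, and second-rank
    (P2) segmental order parameters for lipid tails. Reads and writes GRO
    coordinate files, GROMACS TRR trajectories and a plain-text trajectory
    dialect, and ships a seeded synthetic trajectory generator that plants
    ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
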