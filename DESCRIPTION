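Package: mlcbos
Title: Beam Orientation Selection for MLC-Based Robotic SABR Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Inverse treatment planning and beam orientation selection for
    stereotactic ablative body radiotherapy (SABR) delivered by a robotic
    linear accelerator with a multileaf collimator (MLC). Provides a synthetic
    voxel phantom with priority-resolved structure overlap, candidate beam-node
    generation on a non-coplanar workspace, a pencil-kernel dose engine
    producing sparse dose-influence matrices, quadratic min/max-dose objective
    with projected L-BFGS fluence optimisation, MLC sweep sequencing with
    aperture-weight optimisation, a nested evolutionary algorithm that selects
    a small beam subset with full inverse planning of every candidate plan,
    and plan quality metrics (DVH, conformity index, monitor units, estimated
    treatment time, clinical constraint reports).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
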