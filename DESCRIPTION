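Package: poseoverlap
Title: Volume Overlap, Shape Similarity and Activity Classification for
    Docked Ligand Poses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of rigid docked ligand poses that share a
    receptor-fixed coordinate frame: van der Waals union and intersection
    volumes by deterministic grid or Monte Carlo integration, percent-overlap
    similarity and cross matrices for binding-site co-localization analysis,
    normalized molecular volumes, Gaussian shape and pharmacophore (color)
    Tanimoto ranking against a lead compound, a two-variable linear
    discriminant classifier of propidium displacement with exhaustive
    leave-one-out jackknifing, correlation of docking binding energies with
    graded inhibition endpoints (Pearson, D'Agostino-Pearson normality,
    Steiger's test for dependent correlations), and a seeded synthetic study
    generator that emulates multi-site docking data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ChemmineR,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
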