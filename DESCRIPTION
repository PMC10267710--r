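Package: tibia3d
Title: Bone-Centered 3D Angular Measurements of the Canine Tibia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes canine tibial torsion and varus/valgus angles from
    named anatomical reference points in CT data using a bone-centered
    orthogonal 3D coordinate system, with positioning-independent readouts
    in the 180-degree-neutral convention. Includes landmark file readers and
    writers (native JSON, CSV, 3D-Slicer-style fiducial CSV), a parametric
    synthetic tibia with torsion and angulation hinges for validation,
    method-comparison statistics (Bland-Altman, Passing-Bablok regression,
    within-subject coefficient of variation), and packaged measurement
    tables with one-command replication of the published validation
    results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
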