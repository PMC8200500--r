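Package: epidqa
Title: Vendor-Independent Linac QA Plan Generation and EPID Portal Image
    Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds periodic linear-accelerator quality-assurance plans
    (open field, jaw junction, light-radiation coincidence, picket fence,
    Winston-Lutz, VMAT dose-rate/gantry-speed and MLC-speed tests) as
    control-point sequences serialized to DICOM RT-Plan or a JSON field
    instruction format, renders synthetic EPID portal images for those
    plans with configurable delivery errors, and analyzes portal images:
    junction intensity statistic, ball-bearing based light-radiation
    coincidence, picket-fence leaf-position detection, VMAT band
    statistics, 2D gamma evaluation and Winston-Lutz offsets, with
    tolerance evaluation, JSON reports and error-injection sensitivity
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Software, QualityControl
RoxygenNote: 7.3.3
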