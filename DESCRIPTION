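Package: ranoedema
Title: RANO-BM Response Assessment and Peritumoral Edema Volumetrics for
    Irradiated Brain Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Longitudinal response assessment of stereotactically irradiated
    brain metastases from segmentation masks or pre-measured tables.
    Computes RANO-BM two-dimensional diameters (longest axial diameter and
    in-slice perpendicular) and three-dimensional peritumoral edema volumes
    from binary masks with voxel spacing, assembles per-lesion follow-up
    series over standard post-treatment windows, classifies per-lesion
    response (CR/PR/SD/PD/new lesion), grades edema volume change with a
    25% band, labels core-versus-edema congruence and trajectory patterns
    (continuous change, waxing-and-waning, paradoxical early increase,
    remission), and reproduces the cohort statistics (median/IQR window
    summaries, exact and approximate rank tests, Spearman correlation).
    A calibrated synthetic-cohort generator and geometric phantoms make the
    whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
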