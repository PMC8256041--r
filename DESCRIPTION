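Package: tcrmech
Title: Interdomain Contact Occupancy and Single-Molecule Force Spectroscopy of T Cell Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the two biophysical signatures used to decide whether a
    T cell receptor (TCR) behaves as a mechanosensor. For molecular dynamics
    trajectories of TCR ectodomains it detects hydrogen-bond and nonpolar
    interdomain contacts with distance/partial-charge cutoffs, computes contact
    occupancy in overlapping time windows, counts high-occupancy contacts per
    interface and compares constructs; it also computes Shrake-Rupley solvent
    accessible and buried surface areas for domain interfaces. For optical-trap
    single-molecule traces it segments loading, dwell and rupture phases,
    detects conformational-transition steps, builds force-lifetime curves with
    SEM, fits a dual-pathway (catch/slip) Bell model to bond lifetimes, and
    computes the specific/nonspecific sensitivity index. Includes synthetic-data
    generators with known ground truth for both pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
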