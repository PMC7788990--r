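Package: distval
Title: Evaluation and Visualization of Predicted Protein Inter-Residue Distances
Version: 0.1.0
Authors@R: person("distval", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Scores predicted inter-residue contacts, real-valued distance
    maps, and binned distograms against a true protein structure. Parses
    CASP RR text formats (classic and RMODE 1/2), PDB coordinate files,
    dense '.npy' distance matrices and archived distogram tensor bundles;
    computes MAE, RMSE, Pearson correlation, Cbeta-LDDT at sequence
    separations 6/12/24 and top-L / top-L/5 contact precision for long and
    medium-plus-long ranges; renders combined predicted/true heatmaps and
    chord diagrams; and generates seeded synthetic structures, noisy
    predictions and distograms so the whole pipeline is testable without
    external data. A command-line interface mirrors the library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
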