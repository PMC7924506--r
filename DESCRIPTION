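Package: mspgrid
Title: Grid-Based Maritime Use Conflict and Cumulative Effects Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Grid-based geospatial modelling toolkit for marine spatial
    planning and environmental management. Implements Maritime Use Conflict
    (MUC) analysis, in which COEXIST-style attribute rules score the
    potential conflict of every pair of co-occurring human uses of the sea
    on a regular analysis grid, and Cumulative Effects Assessment (CEA), in
    which use intensities are propagated into pressure fields with Gaussian
    kernels and combined with environmental-component layers through a
    pressure-by-receptor sensitivity matrix. Provides a rectified-grid
    raster engine (rasterization, normalization, log scaling,
    reclassification, Gaussian convolution, masking), a safe map-calculator
    expression language for layer pre-processing, a self-contained
    case-study bundle format with loading, validation and subsetting, a
    deterministic synthetic case-study generator, statistical summaries and
    report writing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    mgcv,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
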