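Package: tlsmat
Title: Tertiary Lymphoid Structure Maturation Classification from Dual
    CD21/CD23 Immunohistochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying the maturation stage of tertiary lymphoid
    structures (TLS) -- Aggregate, Non-GC TLS, or germinal-center (GC) TLS --
    from dual CD21/CD23 immunohistochemistry whole-slide images.  Provides
    annotation-driven extraction of non-overlapping 224x224 tiles from
    QuPath-exported GeoJSON polygons, a pluggable three-class tile classifier
    with a small CPU-trainable reference backbone, seven tile-to-structure
    aggregation methods (majority, average, median, mode, soft voting,
    maturity-priority custom rule, max confidence), patient-stratified k-fold
    cross-validated evaluation with confusion matrices and Cohen's kappa, and
    color-coded tile mosaics.  A synthetic dual-chromogen IHC image generator
    with known ground truth makes the whole pipeline testable without slide
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    e1071,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
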