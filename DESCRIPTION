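Package: petalhue
Title: Hue-Based Flower Color Annotation with a Controlled Color Vocabulary
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for annotating flower color from specimen photographs.
    Averages the color of masked petal regions to a single 8-bit sRGB triple,
    converts RGB to HSV, maps hue degrees onto a bipolar -60..40 scale cut at
    red so that blue sits near zero, and classifies hues into principal and
    intermediate color terms anchored to Phenotypic Quality Ontology (PATO)
    and Encyclopedia of Life (EOL) identifiers. A survey pipeline samples
    specimen image records by locality, computes per-species and overall hue
    medians, bins species medians into a bipolar-scale histogram, and exports
    URI-bearing annotations. A synthetic-data module generates flower images
    with known petal color and survey record tables with known ground truth,
    so every stage is testable without image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
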