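Package: nucleicam
Title: Nuclei Detection in Histology Tiles via Segmentation Saliency Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects individual cell nuclei in hematoxylin-and-eosin
    histology tiles by computing gradient-weighted class activation maps
    (Grad-CAM) over a semantic segmentation network and locating regional
    maxima of the saliency map after grayscale dilation; touching nuclei
    inside one mask component are separated by K-means on pixel
    coordinates. Ships a compact trainable encoder-decoder reference
    network, centroid-matching detection metrics (precision, recall, Dice,
    count errors) with a distance-threshold matching algorithm, fusion of
    two detectors under a proximity rule, readers and writers for
    vertex-list contour XML, centroid CSV and label images, a seeded
    synthetic H&E-like tile generator with exact ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    xml2,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
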