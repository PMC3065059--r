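Package: calculoscope
Title: Automated Recognition of Prostatic Calculi in Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments glandular lumina in prostate histology micrographs with
    a gray-value local-entropy transform, Otsu thresholding and mathematical
    morphology, extracts suspicious calculus regions, describes each region
    with 70 gray-level co-occurrence matrix (GLCM) texture statistics, and
    classifies regions as calculus versus non-calculus with principal
    component analysis feeding a radial-basis-function support vector
    machine, evaluated by repeated 5-fold cross-validation. Includes a
    synthetic phantom generator with ground-truth masks so the whole
    pipeline can be exercised without archived slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
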