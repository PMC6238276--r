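Package: wheatcount
Title: Wheat Seedling Counting from Field Images at Early Leaf Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the number of wheat seedlings per square metre from RGB
    field photographs taken during the first to third leaf stages. A white
    1 m x 1 m frame placed in the scene is located by colour thresholding,
    its corners are found from Freeman chain-code boundary curvature, and the
    enclosed target area is rectified by a four-point perspective transform.
    Seedlings are segmented with an excess-green index, Otsu thresholding and
    morphological cleanup; coverage degree and Harris angular-point counts are
    extracted and fed to per-stage linear models or a unified multi-factor
    model with variety and leaf-age corrections. Includes stepwise-regression
    calibration machinery and a synthetic field-scene generator with ground
    truth so the full pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
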