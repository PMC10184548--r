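Package: paleoneuro
Title: Quantitative Palaeoneurology of Theropod Endocasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mesh-based endocast volumetrics and sensory inference for fossil
    archosaurs. Computes enclosed volumes of watertight triangle meshes
    (STL/OBJ/PLY), reptile encephalisation quotients from endocast volume and
    femoral-circumference body-mass estimates, hearing-frequency estimates
    from cochlear-duct length scaled to basicranial length, olfactory-bulb
    ratios, and midbrain elongation indices; ships transcribed comparative
    reference tables for theropods and a synthetic-data generator with
    analytically known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
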