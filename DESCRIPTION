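Package: infoconn
Title: Informational Connectivity Mapping for fMRI Multi-Voxel Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies, for every time-point of a multi-run block-design fMRI
    session, how discriminable a condition's multi-voxel activity pattern is
    within a region (leave-one-run-out correlation-classifier discriminability),
    and maps brain areas whose discriminability time-courses are synchronized
    with a seed region (informational connectivity). Includes a matched
    seed-based functional-connectivity baseline, mask-aware Gaussian smoothing,
    Fisher transforms, block-permutation cluster-corrected group inference, and
    a synthetic block-design generator with controllable informational and
    univariate coupling between regions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
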