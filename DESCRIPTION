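Package: bronchosum
Title: Summarization of Bronchoscopy Video Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to condense bronchoscopy video recordings into short,
    diagnostically meaningful summaries. Frames are classified as informative
    or non-informative from the sparsity of their thresholded 2-D discrete
    cosine transform spectrum; frames showing airway bifurcations are found
    by counting large dark lumen regions with morphological segmentation;
    per-frame labels and physician annotations are assembled into a budgeted
    edit decision list honouring a configurable compression ratio and minimum
    summary length. A synthetic endoscopy-frame generator and a benchmark
    harness make the whole pipeline testable without clinical data.
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
    optparse,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    graphics,
    grDevices,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
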