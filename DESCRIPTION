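Package: bamscape
Title: Composition, Metabolic and Morphological Analytics for Border-Associated Macrophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for studying the decline of border-associated
    macrophages (BAM) in Alzheimer's disease from single-cell composition
    tables, clinical covariates, Compass-style metabolic reaction penalties
    and multi-channel fluorescence image stacks. Implements cluster
    enrichment scoring, the exponential BAM2:BAM1 ratio score, Hampel-filter
    outlier flagging, linear models of macrophage frequency against clinical
    covariates, metacell pseudobulking, penalty-to-flux transformation with
    Cohen's d subsystem enrichment, healthy-to-AD transition distances, and
    the rolling-ball/area-fraction image quantification used for amyloid and
    cerebral amyloid angiopathy, together with a synthetic-data generator
    with recorded ground truth for end-to-end validation.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
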