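Package: dendplast
Title: Compartmentalized Dendritic Plasticity Analysis and Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipelines and models for studying learning-related
    plasticity compartmentalized between tuft and basal dendrites of cortical
    layer 2/3 pyramidal neurons. Provides a two-photon calcium imaging
    pipeline (frame registration, ROI extraction, dF/F, Savitzky-Golay
    smoothing, 3xSD response detection, peak and normalized-integral
    statistics, sister-branch co-activity), somatic whole-cell voltage
    analysis (spike detection, subthreshold envelope integrals, tone-window
    firing rates), fear-conditioning freezing-score analysis, a composite
    two-sigmoid reduced neuron model with genetic-algorithm fitting, a
    reduced multicompartment biophysical model with NMDA/AMPA synapses, exact
    small-sample nonparametric tests, and a synthetic-data generator that
    emulates the statistical structure of such experiments for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    pracma,
    Rcpp,
    signal,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
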