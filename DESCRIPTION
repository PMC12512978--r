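Package: thalaseg
Title: Thalamic Atlas Comparison and Motor-Sensory Segmentation for Deep
    Brain Stimulation Targeting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for comparing thalamic atlases and segmentation
    techniques in the context of deep brain stimulation (DBS) targeting
    for essential tremor. Provides iterative closest point (ICP)
    co-registration of thalamic label volumes, inter-atlas Dice overlap
    tables, atlas-based (ABS) and diffusion-tensor-based (DTIBS)
    segmentation of patient thalami into motor and sensory regions,
    geometric feature extraction, volume-of-tissue-activated (VTA)
    overlap scoring, and paired Wilcoxon signed-rank statistics with
    Bonferroni-Holm adjustment. A synthetic-data generator produces
    atlases, patient thalami, diffusion tensor fields, and VTA masks
    with known ground truth so that the complete analysis runs without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    mclust,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
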