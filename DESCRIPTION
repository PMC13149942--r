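Package: spikescan
Title: Digital Phenotyping of Wheat Spikes from Images
Version: 0.1.0
Authors@R: person("Repo", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative description of wheat spikes from single-spike
    photographs taken against a uniform blue background. Provides a synthetic
    spike phantom generator with exact ground truth, classical colour/thickness
    segmentation into background, colour chart, spike body and awns, scale and
    colour calibration from a reference chart, morphometric features (spike
    outline descriptors and a symmetrized quadrangle model of the spike body),
    mean and dominant colour features in four colour spaces, grey-level
    co-occurrence and run-length texture features, assembly of per-spike
    multi-view digital certificates with group comparison statistics and
    polygon-model rendering, and a lightweight relational datastore with batch
    import for plant collections.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
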