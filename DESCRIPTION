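Package: diffwire
Title: Differential Wiring Analysis of Weighted Gene Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-condition weighted gene co-expression network analysis with
    differential network inference. Builds condition-specific networks from
    biweight midcorrelation with soft thresholding and the topological
    overlap measure, detects modules by average-linkage clustering with a
    tree cut, derives consensus modules from the entrywise minimum of the
    condition networks, and evaluates module quality and cross-condition
    preservation by permutation Z statistics. Identifies differentially
    expressed (moderated t), differentially variable (variance F test), and
    differentially wired genes (per-edge Fisher r-to-z comparison with a
    per-gene binomial changed-edge null), tests modules for enrichment of
    affected genes, calls differentially wired hub genes, and relates module
    eigengenes to numeric sample traits. Includes a synthetic-data generator
    that plants known modules, rewired hubs, mean shifts, variance changes,
    and trait drivers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
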