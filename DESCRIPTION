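Package: pollweb
Title: Quantitative Plant-Pollinator Network Analysis Along Urbanisation Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative bipartite plant-pollinator interaction webs
    from tabular flower-visitation records, computes network- and
    morphotype-level indices (interaction evenness over realised links,
    qualitative and Shannon-weighted visitor generalism), and a
    flower-constancy based reproductive-success index for plant species and
    floral functional groups. Includes the supporting statistics for
    urbanisation-gradient field designs (Pearson chi-squared homogeneity
    tests, Bray-Curtis similarity, Mantel permutation test for spatial
    autocorrelation, and permutation comparisons of per-web metrics across
    landscape contexts), a calibrated synthetic visitation-data generator,
    and an end-to-end analysis pipeline with plain-text reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
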