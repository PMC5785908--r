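Package: scuba
Title: Scalable Positive-Unlabelled Multiple Kernel Learning for Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate disease genes by integrating heterogeneous gene
    networks through graph node kernels (Markov exponential diffusion, Markov
    diffusion, regularized Laplacian and heat diffusion) combined by a scalable
    margin-distribution multiple kernel learning solver adapted to the
    positive-unlabelled setting, where only known disease genes carry reliable
    labels. Includes network construction from edge lists, co-expression and
    pathway co-participation data, leave-one-out and rank-based evaluation
    protocols with the Hanley-McNeil and Wilcoxon signed-rank tests, and a
    planted-module synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: pROC, stats, utils, graphics
Suggests: testthat (>= 3.0.0), pracma, withr, optparse, yaml, jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
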