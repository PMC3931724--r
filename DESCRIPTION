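Package: coresig
Title: Core Gene-Signature Discovery, Validation and Metagene Scoring
Version: 0.1.0
Author: coresig authors
Maintainer: coresig authors <coresig@users.noreply.github.com>
Description: Discovers "core" genes that recur across a collection of gene
    signatures more often than expected under a size-matched randomization
    null, validates candidate signatures on labeled expression data by PCA
    centroid-separation permutation testing against class-label and
    random-gene-set nulls, and builds a median-PC1-loading metagene model to
    score new datasets, with trend and multi-group rank tests. Includes
    synthetic-data generators (planted-core signature collections, two-class
    expression matrices, multi-dataset families with shared samples, and
    time series with monotone signal) so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
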