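Package: divprof
Title: Similarity-Scaled Diversity Profiles for T-Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes two-parameter diversity profiles D(q, lambda) for T-cell
    receptor CDR3beta repertoires, sensitive simultaneously to clone-size
    distribution (Hill order q) and to pairwise sequence similarity (kernel
    scale lambda). Provides clone-table input/output with frequency-preserving
    subsampling, chunked all-against-all distance matrices under a BLOSUM45
    global-alignment metric or an Atchley-factor embedding metric, naive and
    similarity-scaled Hill diversities evaluated in log space, scalar profile
    features (areas between lambda curves, small-lambda spacing, q-slopes),
    cohort stratification (PCA, complete-linkage clustering, partitioned
    leave-one-out classification, clone-size randomisation control), and a
    seeded synthetic-repertoire generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    pracma,
    randomForest,
    rlang,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
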