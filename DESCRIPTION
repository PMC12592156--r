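Package: speechtrack
Title: Temporal Response Functions and Phoneme-Related Potentials for
    Continuous-Speech EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the brain tracks continuous speech with
    electroencephalography. Implements ridge-regularized lagged regression
    for forward (encoding) and backward (decoding) temporal response
    functions with leave-one-out cross-validated regularization, four
    canonical speech representations (Hilbert envelope, phoneme onsets,
    phonemic surprisal from a frequency-weighted pronunciation lexicon, and
    word-embedding semantic dissimilarity), phoneme-related potentials
    averaged by phoneme and manner of articulation, and the group-level
    statistics used to compare listener cohorts: mass-univariate t-tests
    with false-discovery-rate correction, longest significant intervals,
    channel dominance maps, label-permutation tests with Hedges' g, and
    N1/P2/N2 peak extraction. A synthetic-cohort generator with known
    ground-truth response kernels makes every stage testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
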