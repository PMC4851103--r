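Package: mcevent
Title: Unsupervised Event Characterization and Detection in Multichannel Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised characterization and detection of events (such as
    EEG artifacts) in multichannel recordings. A window slides along the
    signal and each window is summarized by its per-channel second-order
    autoregressive (Burg) coefficients; windows are grouped by average-linkage
    hierarchical clustering on Euclidean distances. The cophenetic correlation
    coefficient gates the minimum usable window size, and the S_Dbw cluster
    validity index drives a joint search over window size and cluster count.
    Runs of consecutive same-cluster windows are converted to localized,
    time-stamped events with durations and per-type frequencies. Includes an
    incremental mode that classifies new window batches against a reference
    clustering, a synthetic multichannel signal generator with planted
    autoregressive event regimes and ground-truth labels, EDF and CSV input,
    and PCA displays of the clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'signal-io.R'
    'windowing.R'
    'cluster-metrics.R'
    'search.R'
    'events.R'
    'pca.R'
    'synth.R'
    'mcevent-package.R'
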