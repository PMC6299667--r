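Package: capscore
Title: Automatic Scoring of Cyclic Alternating Pattern Components in Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-second scoring of the cyclic alternating pattern (CAP) of
    NREM sleep from a single monopolar EEG channel. Decomposes the signal
    into the conventional frequency bands with causal Butterworth filters,
    extracts 55 per-second descriptors (band amplitudes and the
    macro-micro structure descriptor, Teager energy, zero-crossing rate,
    Lempel-Ziv complexity, short-time Fourier descriptors, empirical mode
    decomposition levels, Shannon entropy, Higuchi fractal dimension and
    variance), conditions them (causal smoothing, outlier replacement,
    min-max normalisation), ranks or projects them (mRMR, PCA), and
    classifies each second as background (B) or an A-phase subtype
    (A1, A2, A3) with discriminant analysis, k-nearest neighbours or
    one-against-all support vector machines. Includes a synthetic
    multi-subject EEG generator with planted A-phases, duration
    post-filtering of predictions, and leave-one-subject-out evaluation
    reporting sensitivity, specificity, accuracy and weighted accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    class,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
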