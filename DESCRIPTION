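Package: spikeinfo
Title: Information-Theoretic Analysis of Stimulus Coding in Neuronal Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how populations of simultaneously recorded
    cortical neurons encode sensory stimuli. Converts spike trains and stimulus
    event times into per-trial spike counts and binned spike patterns, estimates
    mutual information between stimuli and responses with limited-sampling bias
    correction (quadratic extrapolation and jackknife), decomposes ensemble
    information into linear, signal-similarity and noise-correlation components,
    decodes stimuli trial-by-trial with cross-validated linear discriminant
    analysis, and builds ensemble-size information curves with redundancy
    measures. Includes a synthetic-session generator emulating whisker-deflection
    protocols in barrel cortex (principal- versus neighbouring-whisker tuning,
    frequency adaptation, shared-gain noise correlations) so every analysis runs
    end-to-end without external recordings, plus the permutation-based testing
    layer used for group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
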