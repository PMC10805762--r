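Package: phonorf
Title: Phonemic Abstraction in Intracranial Speech Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying phonemic abstraction in
    intracranial responses to continuous speech. Provides a synthetic
    stimulus and neural-channel generator with planted ground truth
    (including an acoustically neutralized phoneme pair), band-power
    preprocessing of local field potentials, sliding-window ANOVA
    classification of surface (acoustic) versus underlying (phonemic)
    response sites with a permutation null over arbitrary phone splits,
    a seven-model linear mixed-effects encoding family ranked by AIC and
    Akaike weights, and first- and second-order Maximum Noise Entropy
    receptive-field estimation with jackknife averaging, early stopping,
    and spectrum-preserving shuffle controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
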