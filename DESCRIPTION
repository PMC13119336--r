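Package: synkin
Title: Multi-Digit Motor Synergy Formation from Keypress Pose Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying how multi-digit motor synergies
    form during early learning of a sequential keypress skill. Reads
    markerless-pose digit trajectories and keypress logs, applies confidence
    filtering and gap interpolation, extracts Morlet-wavelet amplitude
    features at five movement frequencies, embeds frames with UMAP and
    segments them into density-defined synergy clusters with an explicit
    noise label, computes per-synergy kinematics (keypress count and rate,
    duration, inter-digit overlap) and a usage-class taxonomy, fits the
    exponential learning curve with micro-online/offline gain decomposition,
    and quantifies synergy-map reorganization with Jensen-Shannon divergence,
    pooled-label permutation tests and Stouffer meta-analytic combination.
    Includes a synthetic-session generator with planted coordination regimes
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    FNN,
    igraph,
    uwot,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
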