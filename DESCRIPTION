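Package: nuscs
Title: Compressed-Sensing Reconstruction of Non-Uniformly Sampled NMR Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of non-uniformly sampled (NUS) free induction
    decays with the classic compressed-sensing algorithm family used in
    biomolecular NMR: CLEAN (matching pursuit), orthogonal matching pursuit,
    iterative soft thresholding in its data-balancing (IST-D) and
    data-preserving (IST-S) variants, iteratively reweighted least squares
    for lp-norm minimization, and low-rank Hankel matrix reconstruction via
    an augmented-Lagrangian scheme with singular value thresholding.
    Includes sampling-schedule diagnostics (point spread function, matrix
    coherence, s-column coherence, the greedy exact-recovery guarantee),
    a seeded Lorentzian signal simulator, Virtual Echo and zero-filling
    preprocessing, and reusable pitfall experiments: residual-vs-sampling
    curves, parameter-missetting scenarios, FID extrapolation, L-curve and
    cross-validation parameter selection, and residual re-addition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
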