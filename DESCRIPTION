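Package: ptxshim
Title: Sequence-Level Parallel-Transmit RF Shimming for Balanced SSFP MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint optimization of complex per-channel RF shim weights and
    balanced steady-state free precession (bSSFP) sequence timing. The
    repetition time (TR) is minimized subject to local and whole-body
    specific absorption rate (SAR) limits, per-channel peak and average
    power limits, and an amplifier gating duty-cycle limit, while the mean
    flip angle within a region of interest is held at target. Includes
    Q-matrix SAR evaluation with virtual observation point (VOP)
    compression, magnitude-least-squares shimming by variable exchange
    with an interior-point convex subproblem solver, a nested
    derivative-free search over pulse duration, and a synthetic
    electromagnetic phantom generator producing multi-channel transmit
    sensitivity maps with physically consistent Q-matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
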