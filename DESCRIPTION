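Package: nervestretch
Title: Biomechanics and Electrophysiology of Peripheral Nerve Stretch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking peripheral nerve biomechanics to
    electrophysiological function during ex vivo axial stretch. Extracts
    compound action potential (CAP) amplitude and latency from stimulus-locked
    voltage recordings, computes Cauchy stress from force and geometry, fits
    the two-parameter polynomial (Raghavan-Vorp) hyperelastic constitutive
    model per specimen, builds smoothing-spline maps between stretch ratio and
    percent CAP amplitude reduction with cohort confidence intervals, analyses
    collagen fiber-angle distributions (1-degree histograms, full width at
    half maximum), and solves a reduced nonlinear finite-element rod model
    that predicts stretch-induced CAP reduction on arbitrary axisymmetric
    nerve geometries. A synthetic-data module generates full cohorts (raw CAP
    traces, force-stretch tables, fiber angles) with the statistical structure
    the analysis assumes, so the whole chain is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    signal,
    car
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
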