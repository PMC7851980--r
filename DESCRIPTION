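Package: colecole
Title: Time- and Frequency-Domain Characterization of Cole-Cole Dielectric Relaxation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Debye, Cole-Cole, Cole-Davidson and Havriliak-Negami
    dielectric relaxation models used in bioimpedance and dielectric
    spectroscopy. Provides a numerical evaluator for the one- and two-parameter
    Mittag-Leffler function on the negative real axis, exact time-domain
    response and relaxation functions with their Curie-von Schweidler and
    Kohlrausch-Williams-Watts asymptotes, step current and charge responses of
    a dielectric-filled parallel-plate capacitor including the constant-phase
    element limit, discrete Gruenwald-Letnikov fractional derivatives for
    verifying the fractional Zener constitutive law, two independent numerical
    inverse Laplace transforms as cross-checks, and nonlinear least-squares
    estimation of model parameters from complex permittivity spectra or
    relaxation records, with a synthetic-data generator for both.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
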