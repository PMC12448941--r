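Package: lfpcoupling
Title: Structure-Function Coupling of Deep-Brain LFP Transmission and
    Diffusion Tractography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relating intrinsic signal transmission in deep-brain
    local field potential (LFP) recordings to white-matter microstructure
    measured by diffusion tractography. The package conditions multichannel
    depth-electrode recordings (harmonic notch filtering, high-pass
    filtering, adjacent-contact bipolar montage), estimates regularized
    empirical transfer functions between bipolar channel pairs by Welch
    cross-spectral averaging, and extracts transmission features (maximum
    gain, roll-off frequency, peak-to-floor ratio). Tract-level structural
    measures (fractional anisotropy, axial diffusivity, fibre count per
    unit area, fibre length) are computed from diffusion-tensor eigenvalues
    and streamline geometry. A random-intercept linear mixed-effects stage
    with outlier filtering, collinearity screening, Satterthwaite t-tests
    and Bonferroni adjustment quantifies the coupling between the two
    domains. A seeded synthetic-data module generates LFP sessions with
    known linear-time-invariant transmission, tensor triples with
    controlled anisotropy, and subject-clustered coupled datasets with
    known regression coefficients, so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
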