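Package: epighost
Title: Echo-Planar Imaging Simulation and Reference-Scan Ghost Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of spin-echo echo-planar imaging (EPI) on a
    small-bore system with an unshielded gradient coil. Models multi-exponential
    eddy-current gradient fields and the B0 shift they induce, builds one-shot,
    interleaved multishot and 3D EPI gradient waveforms and k-space
    trajectories, synthesizes raw echo trains from analytic disk phantoms,
    simulates the delay-swept gradient-echo eddy-current measurement with
    bi-exponential fitting, and implements the reference-scan correction
    (echo-peak resampling plus zeroth-order phase correction) with FFT
    reconstruction and an N/2 Nyquist-ghost metric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    rlang,
    yaml,
    RNifti,
    tiff,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
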