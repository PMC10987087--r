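Package: adfc
Title: Adaptive Delayed Feedback Control for Desynchronising Neuronal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Closed-loop neuromodulation toolkit for suppressing pathological
    synchronous oscillations in spiking neuronal networks. Implements delayed
    feedback control (DFC), its adaptive variant (aDFC) that re-estimates the
    oscillation period online from detected network bursts, and an open-loop
    Poisson stimulation protocol. Provides the spike-train activity metrics
    used to quantify stimulation effects (chi synchrony, population firing
    rate, oscillation intensity as the SNR of the firing-rate power spectrum,
    and wavelet spectrograms), an Izhikevich spiking-network testbed for
    mapping network controllability across excitatory/inhibitory balance and
    synaptic weight scale, an OFF-ON-OFF trial analysis layer (fold changes,
    MANOVA controllability classification, PCA baseline projection, Gaussian
    mixture state clustering and time-in-asynchronous-state), and synthetic
    generators of quasiperiodic network-bursting spike trains for testing
    the full pipeline without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
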