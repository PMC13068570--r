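Package: betabursts
Title: Beta-Burst Detection and Burst-Behavior Coupling in Continuous EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects transient beta-band (13-30 Hz) bursts in continuous
    multichannel EEG by thresholding complex Morlet wavelet power at six
    times its per-frequency median and discarding events shorter than two
    cycles, then relates the resulting binary burst process to a stream of
    self-paced behavioral events (touchscreen touches). Provides burst
    occupancy topography, touch-locked burst probability with baseline
    correction and suppression/rebound extrema, intra-burst touch rate,
    a burst-behavior timing index on inter-touch intervals, one-sample
    t-maps with Bonferroni correction, spatio-temporal cluster-based
    bootstrap correction, and a ground-truth synthetic EEG generator
    (1/f background plus Hann-windowed burst atoms and coupled touch
    trains) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
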