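Package: beatfdtd
Title: Finite-Difference Time-Domain Simulation of Difference-Frequency
    Ultrasound Voicing in Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A staggered-grid acoustic finite-difference time-domain (FDTD)
    solver for heterogeneous voxel tissue models, built to study whether two
    ultrasonic sources at slightly different frequencies can generate an
    audible beat (difference) frequency inside soft tissue suitable as a
    voicing source for an ultrasonic electrolarynx. Provides a tissue
    acoustic-property registry, voxel-volume I/O and synthetic neck phantoms,
    a Yee (2,4) leap-frog solver with momentum-damping losses, hard disc
    sources with baffles and first-order Mur absorbing boundaries, Courant
    stability checks, microphone recording to calibrated 96 kHz WAV, an
    STFT-Hilbert envelope demodulator, SPL spectra with optional C-weighting,
    harmonic roll-off and spectral-correlation statistics, and a Rosenberg
    type-C glottal pulse generator used as the natural-voicing reference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
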