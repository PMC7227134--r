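Package: retinemd
Title: Eccentric Event Down-Sampling and Spiking Elementary Motion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a retina-inspired, space-variant (eccentric) down-sampling
    of event-camera (AER) streams and a network of spiking elementary motion
    detectors (sEMD) built from time-difference-encoder (TDE) neurons. Provides a
    synthetic moving-bar stimulus generator, eccentric and uniform receptive-field
    grids with event-driven leaky integration, four direction-selective TDE
    populations with a motion-direction decoder covering cardinal and diagonal
    motion, and the characterization suite (direction selectivity, speed tuning,
    spatial firing-rate maps, eccentricity profiles, center-of-mass-of-response
    analysis, bar-length experiments).
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
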