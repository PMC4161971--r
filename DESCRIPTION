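Package: trackmorph
Title: Dual-Frame Place-Field Analysis on Morphing Linear Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hippocampal place-cell recordings from
    morphing linear tracks whose geometry changes while their topology is
    preserved. Provides parametric models of an accordion U-track and a
    protrusion-flip track, occupancy-normalized rate maps computed in the
    room (planar) and track-centric (linear) reference frames,
    configuration-similarity correlation matrices with subdiagonal decay
    curves, and the four cross-configuration correlation comparisons
    (flip, distance, segment, rescaled) for the protrusion manipulation.
    A synthetic-data module simulates alternation behaviour and
    inhomogeneous Poisson place-cell spike trains under competing field
    anchoring hypotheses (planar, elastic linear fraction, segment-bound,
    distance-from-well) so the full analysis is testable end-to-end
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
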