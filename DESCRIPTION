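Package: soundtexture
Title: Two-Stage Spectral Analysis and Synthesis of Sound Textures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis and synthesis of natural sound textures (rain, fire,
    wind, crackling) under a two-stage spectral model of auditory texture
    perception.  A sound is summarized by (i) the 1D amplitude spectrum of
    its waveform and (ii) the 2D amplitude spectrum of its cochlear subband
    envelope matrix, obtained from a 32-channel ERB-spaced filterbank with
    Hilbert envelopes downsampled to 400 Hz and power-law compressed.  The
    package synthesizes phase-randomized noises that preserve the first
    spectrum only (PR) or both spectra (le-PR), and provides objective
    metrics, spectrograms, seeded fixture generators, WAV input/output and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
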