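Package: phonovision
Title: Phonatory Analysis of High-Speed Vocal Fold Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative phonatory analysis of high-speed video of
    vocal-fold replicas: glottal segmentation and area-waveform extraction,
    videokymography with left/right edge tracking, optical-flow motion
    waveforms, fold-trajectory symmetry and phase metrics, and scalar
    phonatory descriptors (fundamental frequency, maximum glottal area,
    phonation onset pressure, sound pressure level). Ships a synthetic
    glottal-video and signal generator with exact analytic ground truth so
    every analysis stage can be validated without raw recordings, plus
    image quantification for common bioassays (dye-diffusion coverage,
    live/dead cell counting, blank-normalised absorbance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, EBImage, tiff, png, signal, yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
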