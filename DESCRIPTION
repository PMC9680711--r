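Package: rsofi
Title: Super-Resolution Optical Fluctuation Imaging Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for super-resolution optical fluctuation imaging (SOFI)
    analysis of blinking-fluorophore movies: temporal moment and cumulant image
    reconstruction via the moment-cumulant recursion, Fourier (trigonometric)
    interpolation onto finer pixel grids, temporal noise filtering across time
    blocks, local dynamic range compression, and photobleaching correction by
    equal-fractional-decay block splitting. Includes a blinking-emitter movie
    simulator with Gaussian point spread function, two-state (telegraph)
    photoswitching, optional photobleaching and camera noise, used as ground
    truth for validating every reconstruction step. Raster input and output is
    multi-page TIFF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
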