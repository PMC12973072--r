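Package: chronotrails
Title: Time-Coded Trail Visualizations of Nematode Locomotion Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of wide-field behavioral recordings of C. elegans
    on solid media into trail stills and videos. Frames are brightness
    normalized, corrected for vignetting by division with a Gaussian-blurred
    average frame, and average-subtracted (absolute differences, so brightfield
    and darkfield recordings both work); the moving pixels are then collapsed
    with a pixel-wise maximum projection over the full recording or a sliding
    temporal window, with acquisition time encoded by a colormap and optional
    fade-out of the oldest track segments. Includes a seedable simulator of
    roaming/dwelling worm locomotion with ground truth for end-to-end testing,
    and a command-line interface. Lossless I/O uses multi-page TIFF and PNG
    sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    tibble,
    yaml,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
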