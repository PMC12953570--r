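Package: edgewave
Title: Edge-Enhanced Wavelet-Attention Networks for Small-Object Pest Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Building blocks, assembly and desk-scale verification tools for a
    single-stage small-object detector aimed at crop-pest imagery. Provides
    edge-enhancing multi-scale backbone blocks, a frozen Haar-wavelet
    foreground/background attention stage, an adaptively weighted bidirectional
    feature pyramid neck, a channel-shuffle/spatial-shift upsampler, full
    network assembly with parameter and FLOP accounting for every ablation
    variant, a synthetic textured-scene generator with YOLO-format label I/O
    and deterministic ratio splitting, and a compact tape-based autodiff engine
    so the assembled network can be smoke-trained and evaluated (mAP@50,
    mAP@50-95) on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
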