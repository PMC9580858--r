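Package: voxcast
Title: Headless Scriptable Raycast Rendering of Multichannel 3-D Microscopy Volumes
Version: 0.1.0
Authors@R:
    person("Mark", "Devlin", email = "mdevlin@example.org", role = c("aut", "cre"))
Description: A headless, fully scriptable volume renderer for multichannel 3-D
    fluorescence microscopy stacks. Volumes are quantized to 8 bits per channel
    with per-channel linear normalization and rendered by perspective raycasting
    with front-to-back alpha compositing. Each channel's intensity mapping is a
    monotonic quadratic transfer function parameterized by dark, medium and
    bright levels. A view-aligned sampling plane provides clipped and oblique
    slice views and quantitative screen-to-voxel picking. All render and view
    state is exposed as JSON documents over a local HTTP control API, enabling
    reproducible keyframed movie generation from any scripting environment.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    httpuv,
    curl,
    callr,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
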