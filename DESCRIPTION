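Package: jointtrack
Title: Joint Bayesian Inference of Emitter Numbers and Superresolved
    Tracks from Fluorescence Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for superresolved single-particle tracking from widefield
    fluorescence timelapse images without relying on fluorophore
    photodynamics.  A joint posterior distribution over the number of
    emitters (via truncated Beta-Bernoulli loads), their three-dimensional
    tracks, the diffusion coefficient, per-frame emitter brightness and
    background photon flux is sampled by Markov chain Monte Carlo.  The
    forward model integrates a defocus-dependent Gaussian point spread
    function over pixels and sub-exposure time points (motion blur) and uses
    a Gaussian EMCCD read-out model.  Includes a synthetic-movie simulator,
    gated track-pairing error metrics (pairing distance, tracking error,
    dual-view tracking error, localization resolution), TIFF/CSV/TrackMate
    XML input and output, and a small command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
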