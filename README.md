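# jointtrack

Superresolved single-particle tracking from widefield fluorescence
timelapse movies, without relying on fluorophore photodynamics.

Conventional tracking pipelines detect spots, localize them, and link
them across frames as separate steps; each step throws away information
the next one needs, which is why they break down when emitters approach
within the diffraction limit (`0.61 λ / NA`, ≈250 nm in the visible
range), drift out of focus, or leave the field of view.  `jointtrack`
instead samples one joint posterior distribution

    P(emitter number, tracks, D, brightness, background | image stack)

by Markov chain Monte Carlo, so every recorded count in every pixel of
every frame simultaneously informs the number of emitters, their 3D
tracks, the shared diffusion coefficient `D`, the per-frame brightness
and the per-frame background.  Motion blur becomes signal: tracks are
resolved at `K` sub-exposure positions per frame, and the expected image
integrates a defocus-dependent Gaussian PSF over each pixel and
sub-exposure in closed form.  The package is aimed at single-molecule
biophysicists who have calibrated EMCCD movies (TIFF) and want
superresolved tracks with honest uncertainties in crowded scenes.

The model in brief:

* EMCCD read-out: `w ~ Normal(μ + ξ u, υ + f ξ² u)` for expected photon
  count `u` — offset `μ`, gain `ξ` (counts/photon), read variance `υ`,
  excess noise factor `f` are calibration inputs.
* Unknown emitter number via a truncated Beta–Bernoulli: `M` model
  emitters with binary loads `b^m ~ Bernoulli(γ/M)`; the inferred count
  is `B = Σ b^m` and the construction admits the formal limit `M → ∞`.
* Motion: Gaussian transition probabilities,
  `Δx ~ Normal(0, 2 D δt)` per coordinate at sub-exposure resolution;
  PSF width `σ(z) = σ0 √(1 + (z/d_z)²)`, so `|z|` is estimated from
  defocus.
* Point estimates: the reported count is the posterior mode over `B`;
  the reported tracks are the highest-posterior sample at that count;
  95% credible intervals are 2.5th–97.5th percentile ranges.

It also implements the track-comparison metrics used to benchmark
trackers: gated pairing distance, tracking error (pairing distance per
reference track per frame), its dual-camera variant (which halves the
per-view error), and mislink-insensitive localization resolution — plus
a synthetic-movie simulator and TIFF/CSV/TrackMate-XML I/O so external
trackers can be scored on identical data.

## Worked example

Simulate the benchmark one-emitter scene (16×16 px of 133 nm, NA 1.49,
22 frames of 100 ms, D = 10⁴ nm²/s, 5000 photons/s, EMCCD noise), run a
desk-scale chain, and score the MAP track against the known truth:

```r
library(jointtrack)

fx  <- make_fixture("one-emitter")
cfg <- validate_config(fx$config$camera, fx$config$optics, fx$config$timing,
                       model_config(M = 20, K = 4, gamma = 5),
                       run_config(iterations = 800, burn_in = 400, seed = 7,
                                  background = "constant",
                                  estimate_brightness = FALSE, fixed_h = 5000))
chain <- run_chain(fx$stack, cfg)
est   <- map_estimate(chain)
est
#> <track_estimate> B_MAP = 1 (log posterior -55200.1)

lateral <- function(ts) { ts$z <- NA_real_; ts }
localization_resolution(lateral(est$tracks), lateral(fx$truth_set))
#> [1] 17.17041
tracking_error(lateral(est$tracks), lateral(fx$truth_set),
               gate_nm(5, fx$config$camera))
#> [1] 17.17041
credible_intervals(chain, "D")
#> [1]  5519.748 16092.391
```

The chain finds exactly one emitter; its MAP track lands within ~17 nm
of the ground truth laterally — an order of magnitude below the 280 nm
diffraction limit of this scenario — and the 95% credible interval for
the diffusion coefficient covers the generating 10⁴ nm²/s.  Tracking
error and localization resolution coincide here because a single
correctly-followed emitter admits no mislinks.  Axial (`|z|`) estimates
are also produced but are intrinsically less precise near focus.

The same pipeline runs from a shell via the bundled CLI script (also
installed under the package's `exec/` directory):

```sh
./exec/jointtrack simulate --fixture one-emitter --out sim/
./exec/jointtrack track    --stack sim/stack.tif --config sim/config.yaml --out run/ --seed 7
./exec/jointtrack evaluate --estimate run/map_tracks.csv --reference sim/truth.csv \
                           --out report.json --gate-px 5 --n-frames 22
```

`track` writes MAP tracks (CSV and TrackMate-compatible XML), the
emitter-count posterior, a resumable plain-text chain archive, and a run
manifest with input digests and the configuration snapshot.

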