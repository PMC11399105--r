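---
title: "Joint inference of emitter numbers and superresolved tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint inference of emitter numbers and superresolved tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointtrack)
```

## The problem

Widefield single-particle tracking asks three entangled questions of a
timelapse fluorescence movie: how many emitters are present, where is each
one in every frame, and which localization belongs to which emitter.
Conventional pipelines answer them sequentially — detect spots, localize
them, link them — and each stage discards information the later stages
would need, which is precisely why they fail when emitters approach within
the diffraction limit, defocus, or leave the field of view.  `jointtrack`
instead samples one joint posterior distribution over the emitter count,
the full 3D tracks, the diffusion coefficient, the per-frame brightness and
the per-frame background, so that every photon in every pixel of every
frame informs every unknown simultaneously.  Motion blur, usually a
nuisance, becomes a source of information: the way an emitter's photons
smear across pixels within one exposure constrains its within-frame motion.

## The generative model

**Camera.**  An EMCCD records, at pixel $p$ in exposure $n$, a count
$w_n^p$ modelled as
$$w_n^p \mid u_n^p \sim \mathrm{Normal}\!\left(\mu + \xi u_n^p,\;
\upsilon + f \xi^2 u_n^p\right),$$
where $u_n^p$ is the expected number of incident photons, $\mu$ the
offset, $\upsilon$ the read-noise variance, $\xi$ the overall gain
(counts/photon) and $f \ge 1$ the excess noise factor of electron
multiplication.  These four numbers are calibration inputs, not inferred.
Because the model is Normal, arbitrary real-valued counts are accepted.

**Pixelization and blur.**  The expected photon count integrates the
photon flux over the pixel's area and the exposure window.  The time
integral is discretized at $K$ midpoint sub-exposure times per frame
(default $K = 4$), and at each sub-position the unit-mass 2D Gaussian PSF
is integrated over the pixel in closed form via differences of the Gaussian
cumulative integral along each axis — pixelation is modelled explicitly,
never approximated by a centre-point evaluation.  Doubling $K$ from 4 to 8
changes expected images by well under 0.1% at the default diffusion and
frame rate, which is why 4 is the shipped default.

**Optics.**  The PSF width grows with defocus as
$\sigma(z) = \sigma_0 \sqrt{1 + (z/d_z)^2}$, an astigmatism-free defocus
model; $\sigma_0$ defaults to $0.21\,\lambda/\mathrm{NA}$.  This functional
form sits behind a single interface (`psf_lateral_width`) and is meant to
be replaceable by a precalibrated form.  Because $\sigma(z)$ is even in
$z$, only $|z|$ is identifiable from a single image plane, and all exports
report $|z|$.  Near focus the width is nearly flat in $z$, so axial
estimates are intrinsically much less precise than lateral ones — a
physical limit, not an implementation artifact.

**Unknown emitter number.**  Following the latent-feature construction,
the model carries $M$ *model emitters* (default 50), each with a binary
load $b^m$; the flux is background plus $\sum_m b^m \times$ (emitter $m$'s
contribution), and the inferred count is $B = \sum_m b^m$.  Loads are
a priori independent Bernoulli$(\gamma/M)$, so the expected count is
$\gamma$ (default 5) at every truncation and the count prior tends to
Poisson$(\gamma)$ as $M \to \infty$.  The truncation must satisfy
$B \ll M$ a posteriori; the count posterior reported by the sampler makes
this checkable.

**Motion.**  Tracks follow Gaussian transition probabilities at
sub-exposure resolution: per-coordinate increments
$\mathrm{Normal}(0,\, 2 D \,\delta t)$, with uniform initial positions over
the field of view expanded by a 2-pixel margin (emitters may sit outside
the FOV and still contribute photons) and $z$ uniform on
$[-z_{\max}, z_{\max}]$, $z_{\max} = 2 d_z$.  A single $D$ is shared by
all active emitters.  Gaussian transitions are deliberately generic: by
the central limit theorem they absorb a range of true motion models, and
the simulator provides directed, confined and immobile alternatives to
probe this robustness.

**Parameter priors.**  Brightness $h_n$ (photons/s) and background flux
$F_n$ (photons nm$^{-2}$ s$^{-1}$) carry independent Gamma priors per
frame — both can drift substantially over an acquisition, and nothing
couples them across frames.  $D$ carries an Inverse-Gamma prior.  The
Inverse-Gamma choice (rather than a Gamma) is deliberate: it is the
conjugate family for the variance of Gaussian increments, which gives the
sampler an exact full-conditional draw for $D$; its shape/scale defaults
(2, $10^4$ nm$^2$/s) put the prior mean at $10^4$ nm$^2$/s with infinite
variance, i.e. weakly informative.

## The sampler

`run_chain` runs a fixed-scan Metropolis-within-Gibbs sweep targeting the
unnormalized log posterior `state_log_posterior`:

1. **Track blocks.**  Each active emitter's track is updated in temporal
   windows of 1, 3 and 7 frames (cycled across sweeps; both jitter and
   drift scales mix).  The proposal is the motion prior conditioned on the
   window's fixed endpoints — a Brownian bridge — so prior and proposal
   cancel and the acceptance ratio reduces to the likelihood ratio on the
   affected frames (plus the initial-position density when the window
   contains the track start).
2. **Whole-track translation.**  A symmetric Gaussian shift of an entire
   active track; the motion prior is translation invariant, so only the
   likelihood and the uniform initial-density support enter.  This repairs
   whole-track offsets that bridge moves fix only diffusively.
3. **Inactive refresh.**  Inactive emitters' tracks are resampled exactly
   from their motion prior (their full conditional).
4. **Loads.**  A random subset of all $M$ emitters receives flip attempts.
   Selecting actives and inactives at *equal* probability is essential:
   attempting deaths more often than births would break detailed balance
   on the loads (this exact defect was caught by the prior-recovery test
   during development).  Births propose a fresh track whose starting
   position comes from a mixture of the uniform prior and Gaussians
   centred on bright pixels; the mixture density enters the acceptance
   ratio exactly, so the data-informed proposal changes mixing speed, not
   the target.  Deaths propose the replacement inactive track from the
   reference-diffusion prior, whose density cancels.
5. **Diffusion.**  An exact Inverse-Gamma full-conditional draw given the
   active tracks' increments, a joint scaling move that multiplies $D$ by
   $c$ and rescales all active increments by $\sqrt{c}$ about each track's
   mean position (motion-prior terms cancel exactly; the Jacobian is
   $c \cdot c^{n/2} \cdot c^{-n/2}$), and two *non-centered bridge* scaling
   moves.  The latter address a funnel: the sub-exposure points between
   consecutive frame anchors carry essentially no information about $D$ —
   their full conditional is the Brownian bridge at the current $D$ — so a
   purely centered sampler lets them pseudo-inform the full conditional and
   under-represents $D$'s uncertainty.  The bridge move proposes
   $D' = cD$ while rescaling each track's deviations about the time-linear
   interpolation between its fixed frame anchors by $\sqrt{c}$; bridge
   densities and Jacobian cancel, leaving the $D$ prior ratio, the
   frame-anchor increment prior ratio (the identifiable information) and a
   mild motion-blur likelihood ratio.  Without this move, credible
   intervals for $D$ come out materially narrower than at $K = 1$ (where
   no within-frame freedom exists) even though the within-frame freedom
   adds no information — the signature of the funnel; with it, interval
   widths at $K = 4$ behave like the $K = 1$ control.
6. **Brightness and background.**  Log-scale random walks per frame (with
   the log-scale Jacobian), or a single constant background when
   configured.  With the likelihood disabled these become exact prior
   draws.

**Inactive tracks and `d_ref`.**  Inactive emitters keep full tracks so
load flips are dimension-preserving (no reversible jump).  Their motion
prior uses a *fixed* reference diffusion `d_ref` (default: the $D$-prior
mean) rather than the shared $D$.  Since inactive tracks integrate out of
the marginal posterior over (loads, active tracks, $D$), this changes
nothing about the inference target for the quantities of interest, but it
decouples $D$'s full conditional from $\sim M$ prior-simulated tracks,
which would otherwise pin $D$ to its current value and stall mixing.

**Validation.**  Three sampler-correctness checks run in the test suite:
(i) with the likelihood disabled, the chain reproduces its priors — the
active count against Binomial$(M, \gamma/M)$ by a chi-squared test (a KS
test is invalid for a discrete variate) and $D$, $h$, $F$ by KS tests;
(ii) conjugate $D$ draws match the analytic Inverse-Gamma quantiles;
(iii) every recorded log posterior equals an independent recomputation
from the stored sample.

**Estimates.**  The reported count $B_{\mathrm{MAP}}$ is the most frequent
count among retained samples, and the reported state is the highest-log-
posterior sample among those with that count (mode first, then maximum;
ties by first occurrence).  95% credible intervals are percentile-based
(2.5th–97.5th).  Because emitter labels are arbitrary across samples,
track credible intervals match each sample's positions to the MAP tracks
frame by frame with a gate-free nearest-position assignment.

## Track metrics

The gated distance between two tracks sums, per frame,
$\min(\lVert\psi_n - \phi_n\rVert, \epsilon)$; a frame where either track
lacks a localization contributes the gate $\epsilon$.  The pairing
distance between two *sets* minimizes the total gated distance over
one-to-one pairings (a linear assignment problem, solved exactly; a track
left unmatched costs $\epsilon N$, consistent with failing localization in
every frame).  Tracking error divides the pairing distance by
$N \times M_{\mathrm{ref}}$; the dual-view variant pairs two cameras'
track sets with an infinite gate and divides by $2 N M$ because the
pairing distance sums both views' errors ($M$ is the mean of the two set
sizes when they disagree; unmatched tracks then contribute nothing to the
numerator — the convention is otherwise underdetermined).  Localization
resolution re-pairs positions frame by frame without identity or gate, so
mislinks do not contribute; it is undefined when per-frame counts differ,
and it aggregates by arithmetic mean per pair-frame (mean rather than RMS
is an open choice; mean matches the tracking error's normalization style,
and the two metrics then coincide exactly when there are no mislinks,
false positives or false negatives).  Comparisons use the shared
coordinates when one side lacks axial positions, and compare $|z|$ with
$|z|$.  Default gate for truth comparisons: 5 pixels (665 nm at 133 nm
pixels); dual-view comparisons use an infinite gate.

## The simulator

`make_fixture` reproduces the benchmark imaging regime: 133 nm pixels,
NA 1.49, 100 ms continuous exposures, 22 frames, Brownian motion at
$D = 10^4$ nm$^2$/s, brightness 5000 photons/s (500 photons per frame per
emitter), background $10^{-2}$ photons nm$^{-2}$ s$^{-1}$ (about 18
photons per pixel per frame), EMCCD offset 100, gain 10, read variance 25,
excess noise 2.  The synthetic-scenario wavelength is 684 nm, chosen so
the nominal diffraction limit $0.61 \lambda / \mathrm{NA}$ equals the
280 nm of the benchmark regime (the experimental regime, NA 1.49 at
565 nm, gives 231 nm).  Ground truth is generated directly at the forward
model's $K$ sub-exposure positions, so rendering is exact with respect to
the model — no hidden discretization gap between generator and inference.

The two-emitter mean-displacement scenes give the second track the same
increments as the first plus a constant offset, so the realized per-frame
mean separation equals the target exactly and a 0 nm target yields
coincident tracks; the equally spaced published displacement series is
consistent with such controlled constant separations, and independent
Brownian pairs could not reach the smallest targets at realistic $D$.  An
`independent = TRUE` mode instead scales the starting offset of an
independent second track iteratively to within 2% and raises an error for
unreachable targets.

What the simulator deliberately does **not** emulate: photophysics
(blinking, bleaching — the method does not rely on it), spatially
structured background, sCMOS-style per-pixel noise maps, optical
aberrations beyond symmetric defocus, and camera saturation.  Passing
tests on these fixtures therefore demonstrates correctness of the
inference under its own model assumptions and robustness to the modelled
noise — not immunity to every artifact of real microscopes.

## Problem sizes and numerical choices

The test suite runs scaled-down studies chosen to exercise the full
pipeline at desk scale: regions of interest of $16\times16$ pixels
(one-emitter) and $24\times24$ pixels (three-emitter and two-emitter
scenes) rather than full fields of view, truncation $M = 20$, and chains
of 350–1500 sweeps with the first half discarded as burn-in.  Coverage
checks use replicate datasets (fresh noise and path realization per run),
the design under which credible-interval coverage is meaningful.  Benchmark
runs fix the brightness at its true value and estimate a constant
background, mirroring the convention of supplying competing tools with
ground-truth photometry while the tracker still infers $D$ and the
background.  Ten-seed repetitions back the count-recovery and
credible-interval coverage checks; coverage of a nominal 95% interval is
asserted at 8/10 to leave room for small-replicate noise.

Other numerical conventions: pixels are half-open rectangles (every point
belongs to exactly one pixel) indexed row-major with the origin at the
outer corner of pixel (1, 1); times are seconds and positions nm
everywhere internally, converted only at I/O boundaries; assignment
problems are solved exactly and deterministically; all randomness in a run
flows from one integer seed, so chains, fixtures and CLI outputs are
bit-reproducible.  `run_chain` aborts on a non-finite log posterior rather
than continuing silently; caches of expected images are rebuilt exactly
before each recorded sample so that stored log posteriors equal fresh
recomputation to $10^{-8}$.

## Known limitations

Credible intervals for $D$ are exact posterior summaries, but their
frequentist coverage at a fixed generating $D$ degrades as the interval
narrows: with several emitters the posterior is tight (roughly ±20%)
while its centre scatters across data realizations by a comparable
amount, because weakly identified axial paths and sub-exposure
localization uncertainty feed into the realized diffusion.  Coverage of
the fixed generating $D$ is therefore easier to attain for one-emitter
scenes (wide intervals) than for multi-emitter scenes (narrow intervals)
at a fixed movie length; this is an information-content property of
22-frame movies, not a sampler artifact.

Axial positions are reported as magnitudes and are weakly identified near
focus.  The shared single $D$ is a modelling choice — per-emitter or
state-switching diffusion belongs to downstream analysis of the sampled
tracks.  Background is spatially uniform within a frame (a documented
extension point).  Runtime scales linearly in pixels, frames and active
emitters; full 5 µm fields of view with tens of emitters are hours-scale
runs, and the desk-scale studies here use the reduced sizes listed above.
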