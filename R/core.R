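#' @keywords internal
"_PACKAGE"

# ---- validation helpers -----------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, positive = TRUE, ge = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a finite numeric scalar")
  if (positive && x <= 0) stop_field(field, "must be > 0")
  if (!is.null(ge) && x < ge) stop_field(field, sprintf("must be >= %s", ge))
  invisible(x)
}

# ---- camera -----------------------------------------------------------------

#' EMCCD camera model
#'
#' Describes the read-out of an electron-multiplying CCD: a recorded count
#' `w` at a pixel receiving on average `u` photons during an exposure is
#' modelled as `w ~ Normal(offset + gain * u, read_variance + excess_noise *
#' gain^2 * u)`.  The excess noise factor accounts for the stochastic
#' electron multiplication; `gain` lumps quantum efficiency, pre-amplification,
#' electron multiplication and quantization into counts per photon.
#'
#' @param offset Camera offset (dark level), counts.
#' @param read_variance Read-out noise variance, counts^2 (> 0).
#' @param gain Overall gain, counts per photon (> 0).
#' @param excess_noise Excess noise factor, dimensionless (>= 1).
#' @param pixel_size Side length of a (square) pixel in the sample plane, nm.
#' @param n_rows,n_cols Sensor geometry of the analyzed region.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(offset = 100, read_variance = 25, gain = 10,
#'                     excess_noise = 2, pixel_size = 133,
#'                     n_rows = 16, n_cols = 16)
#' @export
camera_model <- function(offset, read_variance, gain, excess_noise,
                         pixel_size, n_rows, n_cols) {
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset))
    stop_field("camera.offset", "must be a finite numeric scalar")
  check_scalar(read_variance, "camera.read_variance")
  check_scalar(gain, "camera.gain")
  check_scalar(excess_noise, "camera.excess_noise", positive = FALSE, ge = 1)
  check_scalar(pixel_size, "camera.pixel_size")
  check_scalar(n_rows, "camera.rows", positive = FALSE, ge = 1)
  check_scalar(n_cols, "camera.cols", positive = FALSE, ge = 1)
  structure(
    list(offset = offset, read_variance = read_variance, gain = gain,
         excess_noise = excess_noise, pixel_size = pixel_size,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %d x %d px of %g nm; offset %g, gain %g ct/photon, read var %g, excess noise %g\n",
              x$n_rows, x$n_cols, x$pixel_size, x$offset, x$gain,
              x$read_variance, x$excess_noise))
  invisible(x)
}

n_pixels <- function(camera) camera$n_rows * camera$n_cols

pixel_area <- function(camera) camera$pixel_size^2

# ---- optics -----------------------------------------------------------------

#' Microscope optics model
#'
#' Parameterizes the point spread function (PSF): an emitter at axial
#' distance `z` from the focal plane produces a 2D Gaussian spot of lateral
#' width `sigma(z) = sigma0 * sqrt(1 + (z / dz)^2)`.  `sigma0` defaults to
#' the common Gaussian approximation of the in-focus Airy spot,
#' `0.21 * wavelength / na`.
#'
#' @param na Numerical aperture of the objective.
#' @param wavelength Emission wavelength, nm.
#' @param sigma0 In-focus PSF width, nm.
#' @param dz Axial scale over which defocus doubles the PSF variance, nm.
#' @return An object of class `optics_model`.
#' @seealso [diffraction_limit()], [psf_lateral_width()]
#' @export
optics_model <- function(na, wavelength, sigma0 = 0.21 * wavelength / na,
                         dz = 500) {
  check_scalar(na, "optics.na")
  check_scalar(wavelength, "optics.wavelength")
  check_scalar(sigma0, "optics.sigma0")
  check_scalar(dz, "optics.dz")
  structure(list(na = na, wavelength = wavelength, sigma0 = sigma0, dz = dz),
            class = "optics_model")
}

#' Rayleigh diffraction limit
#'
#' Nominal diffraction limit `0.61 * wavelength / na` of the optics, in nm.
#'
#' @param optics An [optics_model()].
#' @return Length-one numeric, nm.
#' @examples
#' diffraction_limit(optics_model(na = 1.49, wavelength = 565)) # ~231 nm
#' @export
diffraction_limit <- function(optics) {
  stopifnot(inherits(optics, "optics_model"))
  0.61 * optics$wavelength / optics$na
}

# ---- timing -----------------------------------------------------------------

#' Acquisition timing
#'
#' Exposure windows of a timelapse acquisition.  Frame `n` integrates photons
#' over `[t_min[n], t_max[n])`; windows must be strictly increasing and
#' non-overlapping (dead time between exposures is allowed).
#'
#' @param n_frames Number of frames.
#' @param exposure Exposure duration per frame, seconds.
#' @param period Time from one exposure start to the next, seconds
#'   (`>= exposure`); defaults to `exposure` (continuous acquisition).
#' @param t0 Start time of the first exposure, seconds.
#' @return An object of class `acq_timing` with fields `n_frames`, `t_min`,
#'   `t_max`.
#' @export
acquisition_timing <- function(n_frames, exposure, period = exposure, t0 = 0) {
  check_scalar(n_frames, "timing.n_frames", positive = FALSE, ge = 1)
  check_scalar(exposure, "timing.exposure")
  check_scalar(period, "timing.period")
  if (period < exposure)
    stop_field("timing.period", "must be >= timing.exposure (exposures cannot overlap)")
  n_frames <- as.integer(n_frames)
  t_min <- t0 + (seq_len(n_frames) - 1) * period
  acquisition_windows(t_min, t_min + exposure)
}

#' @rdname acquisition_timing
#' @param t_min,t_max Explicit exposure window bounds, seconds.
#' @export
acquisition_windows <- function(t_min, t_max) {
  if (length(t_min) != length(t_max) || length(t_min) < 1L)
    stop_field("timing", "t_min and t_max must be equal-length, non-empty")
  if (any(!is.finite(t_min)) || any(!is.finite(t_max)))
    stop_field("timing", "exposure times must be finite")
  if (any(t_min >= t_max))
    stop_field("timing", "each t_min must be < its t_max")
  n <- length(t_min)
  if (n > 1L && any(t_max[-n] > t_min[-1] + 1e-12))
    stop_field("timing", "exposures overlap: t_max[n] must be <= t_min[n+1]")
  structure(list(n_frames = n, t_min = as.numeric(t_min),
                 t_max = as.numeric(t_max)),
            class = "acq_timing")
}

exposure_durations <- function(timing) timing$t_max - timing$t_min

#' Sub-exposure time grid
#'
#' Midpoint times of the `K` sub-exposure slots of every frame, used both to
#' discretize the motion-blur time integral of the forward model and as the
#' time resolution of ground-truth tracks.
#'
#' @param timing An [acquisition_timing()].
#' @param K Sub-exposure positions per frame (>= 1).
#' @return List with `times` (length `K * n_frames`), `frame` (frame index of
#'   each time) and `dt` (time steps between consecutive grid points,
#'   length `K * n_frames - 1`).
#' @export
subexposure_times <- function(timing, K) {
  stopifnot(inherits(timing, "acq_timing"))
  check_scalar(K, "model.K", positive = FALSE, ge = 1)
  K <- as.integer(K)
  dtk <- exposure_durations(timing) / K
  times <- as.numeric(vapply(seq_len(timing$n_frames), function(n) {
    timing$t_min[n] + (seq_len(K) - 0.5) * dtk[n]
  }, numeric(K)))
  frame <- rep(seq_len(timing$n_frames), each = K)
  list(times = times, frame = frame, dt = diff(times), K = K)
}

# ---- pixel geometry ---------------------------------------------------------

#' Region monitored by a pixel
#'
#' Pixels are indexed row-major (pixel 1 is row 1, column 1), with the
#' spatial origin at the outer corner of pixel (1, 1); `x` runs along
#' columns, `y` along rows.  Regions are half-open rectangles
#' `[x_min, x_max) x [y_min, y_max)` so that every point belongs to exactly
#' one pixel and the regions tile the field of view exactly.
#'
#' @param p Pixel index, `1 <= p <= n_rows * n_cols` (vectorized).
#' @param camera A [camera_model()].
#' @return Matrix with columns `x_min`, `x_max`, `y_min`, `y_max` (nm).
#' @export
pixel_region <- function(p, camera) {
  stopifnot(inherits(camera, "camera_model"))
  p <- as.integer(p)
  if (any(p < 1L | p > n_pixels(camera)))
    stop(sprintf("pixel index out of range 1..%d", n_pixels(camera)), call. = FALSE)
  r <- (p - 1L) %/% camera$n_cols + 1L
  cc <- (p - 1L) %% camera$n_cols + 1L
  ps <- camera$pixel_size
  cbind(x_min = (cc - 1) * ps, x_max = cc * ps,
        y_min = (r - 1) * ps, y_max = r * ps)
}

#' Pixel containing a position
#'
#' Inverse of [pixel_region()]: maps continuous lateral positions (nm) to the
#' index of the pixel whose half-open region contains them, or `NA` for
#' positions outside the field of view.
#'
#' @param x,y Lateral coordinates, nm (vectorized).
#' @inheritParams pixel_region
#' @return Integer pixel indices (row-major), `NA` outside the FOV.
#' @export
pixel_at <- function(x, y, camera) {
  stopifnot(inherits(camera, "camera_model"))
  ps <- camera$pixel_size
  cc <- floor(x / ps) + 1
  r <- floor(y / ps) + 1
  out <- (r - 1) * camera$n_cols + cc
  bad <- cc < 1 | cc > camera$n_cols | r < 1 | r > camera$n_rows
  out[bad] <- NA_integer_
  as.integer(out)
}

fov_size <- function(camera) {
  c(x = camera$n_cols * camera$pixel_size, y = camera$n_rows * camera$pixel_size)
}

# ---- image stack ------------------------------------------------------------

#' Timelapse image stack
#'
#' Recorded camera counts for every pixel and frame, with the acquisition
#' timing and camera model attached.  Counts are stored as a numeric array of
#' dimension `n_rows x n_cols x n_frames`; arbitrary real values (including
#' negatives, e.g. after upstream offset handling) are permitted.
#'
#' @param values Numeric array `n_rows x n_cols x n_frames` (a matrix is
#'   accepted for a single frame).
#' @param timing An [acquisition_timing()].
#' @param camera A [camera_model()].
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(values, timing, camera) {
  stopifnot(inherits(timing, "acq_timing"), inherits(camera, "camera_model"))
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be an n_rows x n_cols x n_frames array", call. = FALSE)
  d <- dim(values)
  if (d[1] != camera$n_rows || d[2] != camera$n_cols)
    stop(sprintf("frame shape %d x %d does not match camera %d x %d",
                 d[1], d[2], camera$n_rows, camera$n_cols), call. = FALSE)
  if (d[3] != timing$n_frames)
    stop(sprintf("stack has %d frames but timing declares %d",
                 d[3], timing$n_frames), call. = FALSE)
  if (any(!is.finite(values)))
    stop("image values must be finite", call. = FALSE)
  structure(list(values = values, timing = timing, camera = camera),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d frames of %d x %d px; counts in [%g, %g]\n",
              x$timing$n_frames, x$camera$n_rows, x$camera$n_cols,
              min(x$values), max(x$values)))
  invisible(x)
}

# values as P x N matrix, pixel index row-major
stack_matrix <- function(stack) {
  v <- stack$values
  d <- dim(v)
  # row-major pixel order: transpose each frame before flattening
  matrix(aperm(v, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

matrix_to_frames <- function(m, camera) {
  aperm(array(m, dim = c(camera$n_cols, camera$n_rows, ncol(m))), c(2, 1, 3))
}

# ---- track set --------------------------------------------------------------

#' Set of emitter tracks
#'
#' A track set stores, for each track and frame, a lateral (and optionally
#' axial) position in nm in the common frame of reference, plus a `present`
#' flag (`FALSE` = the track has no localization in that frame).  All tracks
#' share the frame axis `1..n_frames`; every track must be present in at
#' least one frame.
#'
#' @param df Data frame with columns `track`, `frame`, `x`, `y`, optionally
#'   `z` and `present` (missing `present` defaults to `TRUE`).  Frames absent
#'   from `df` for a given track are treated as not present.
#' @param n_frames Number of frames of the shared axis; defaults to
#'   `max(df$frame)`.
#' @return An object of class `track_set`: a data frame with one row per
#'   (track, frame), columns `track`, `frame`, `x`, `y`, `z`, `present`.
#' @export
track_set <- function(df, n_frames = max(df$frame)) {
  stopifnot(is.data.frame(df))
  need <- c("track", "frame", "x", "y")
  if (!all(need %in% names(df)))
    stop("track data must have columns track, frame, x, y", call. = FALSE)
  if (!"z" %in% names(df)) df$z <- NA_real_
  if (!"present" %in% names(df)) df$present <- TRUE
  df$frame <- as.integer(df$frame)
  if (nrow(df) && (min(df$frame) < 1L || max(df$frame) > n_frames))
    stop("frame indices must lie in 1..n_frames", call. = FALSE)
  ids <- unique(df$track)
  full <- expand.grid(frame = seq_len(n_frames), track = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full <- merge(full, df[c("track", "frame", "x", "y", "z", "present")],
                by = c("track", "frame"), all.x = TRUE)
  full$present[is.na(full$present)] <- FALSE
  full$present <- full$present & is.finite(full$x) & is.finite(full$y)
  for (tr in ids) {
    if (!any(full$present[full$track == tr]))
      stop(sprintf("track `%s` has no present frame", tr), call. = FALSE)
  }
  full <- full[order(match(full$track, ids), full$frame), ]
  rownames(full) <- NULL
  attr(full, "n_frames") <- as.integer(n_frames)
  class(full) <- c("track_set", "data.frame")
  full
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks over %d frames (%s axial)\n",
              n_tracks(x), n_frames(x),
              if (all(is.na(x$z))) "no" else "with"))
  invisible(x)
}

#' Number of tracks / frames of a track set
#' @param ts A [track_set()].
#' @return Integer.
#' @export
n_tracks <- function(ts) length(unique(ts$track))

#' @rdname n_tracks
#' @export
n_frames <- function(ts) attr(ts, "n_frames")

track_ids <- function(ts) unique(ts$track)

# positions of one track as an n_frames x 3 matrix (NA where absent)
track_matrix <- function(ts, id) {
  rows <- ts[ts$track == id, ]
  rows <- rows[order(rows$frame), ]
  m <- as.matrix(rows[c("x", "y", "z")])
  m[!rows$present, ] <- NA_real_
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

# ---- configuration ----------------------------------------------------------

#' Model and run settings
#'
#' Inference settings of the posterior model.  `M` is the truncation level of
#' the Beta-Bernoulli loads prior (number of model emitters, active plus
#' inactive), `gamma` the expected number of active emitters a priori, `K`
#' the number of sub-exposure positions per frame used to resolve motion
#' blur.  Prior scales: D carries an Inverse-Gamma(`d_shape`, scale
#' `d_scale`) prior (prior mean `d_scale / (d_shape - 1)`); per-frame
#' brightness h_n and background flux F_n carry Gamma(shape, scale) priors.
#'
#' @param M Truncation level, >= 1.
#' @param K Sub-exposure positions per frame, >= 1.
#' @param gamma Expected active emitters a priori, 0 < gamma < M.
#' @param d_shape,d_scale Inverse-Gamma prior on the diffusion coefficient
#'   (nm^2/s).
#' @param h_shape,h_scale Gamma prior on per-frame emitter brightness
#'   (photons/s).
#' @param f_shape,f_scale Gamma prior on per-frame background photon flux
#'   (photons/nm^2/s).
#' @param z_max Half-width of the uniform prior on initial axial position,
#'   nm; defaults to `2 * dz` at configuration time when `NULL`.
#' @param fov_margin_px Margin, in pixels, by which the uniform prior on
#'   initial lateral positions extends beyond the field of view.
#' @param d_ref Reference diffusion coefficient (nm^2/s) of the motion prior
#'   carried by inactive model emitters; defaults to the D-prior mean.
#' @return A list of class `model_config`.
#' @export
model_config <- function(M = 50, K = 4, gamma = 5,
                         d_shape = 2, d_scale = 1e4,
                         h_shape = 2, h_scale = 2500,
                         f_shape = 2, f_scale = 5e-3,
                         z_max = NULL, fov_margin_px = 2,
                         d_ref = NULL) {
  check_scalar(M, "model.M", positive = FALSE, ge = 1)
  check_scalar(K, "model.K", positive = FALSE, ge = 1)
  check_scalar(gamma, "model.gamma")
  if (gamma >= M) stop_field("model.gamma", "must be < model.M")
  for (nm in c("d_shape", "d_scale", "h_shape", "h_scale", "f_shape", "f_scale"))
    check_scalar(get(nm), paste0("model.", nm))
  if (!is.null(z_max)) check_scalar(z_max, "model.z_max")
  check_scalar(fov_margin_px, "model.fov_margin_px", positive = FALSE, ge = 0)
  if (!is.null(d_ref)) check_scalar(d_ref, "model.d_ref")
  structure(list(M = as.integer(M), K = as.integer(K), gamma = gamma,
                 d_shape = d_shape, d_scale = d_scale,
                 h_shape = h_shape, h_scale = h_scale,
                 f_shape = f_shape, f_scale = f_scale,
                 z_max = z_max, fov_margin_px = fov_margin_px,
                 d_ref = d_ref),
            class = "model_config")
}

#' @param iterations Total MCMC sweeps.
#' @param burn_in Sweeps discarded from the front (default: half).
#' @param thin Keep every `thin`-th retained sweep.
#' @param seed Integer seed governing the whole run.
#' @param estimate_brightness If `FALSE`, per-frame brightness is held fixed
#'   at its initial value (the protocol used for benchmarking against tools
#'   that receive the true brightness).
#' @param background Either `"per_frame"` (independent F_n) or `"constant"`
#'   (a single background flux for all frames).
#' @param fixed_h Optional known brightness (photons/s) used when
#'   `estimate_brightness = FALSE`.
#' @param n_birth Number of inactive model emitters proposed for activation
#'   per sweep.
#' @rdname model_config
#' @export
run_config <- function(iterations = 1000, burn_in = floor(iterations / 2),
                       thin = 1, seed = 1, estimate_brightness = TRUE,
                       background = c("per_frame", "constant"),
                       fixed_h = NULL, n_birth = 5) {
  check_scalar(iterations, "run.iterations", positive = FALSE, ge = 1)
  check_scalar(burn_in, "run.burn_in", positive = FALSE, ge = 0)
  check_scalar(thin, "run.thin", positive = FALSE, ge = 1)
  check_scalar(seed, "run.seed", positive = FALSE)
  if (burn_in > iterations)
    stop_field("run.burn_in", "must be <= run.iterations")
  background <- match.arg(background)
  if (!is.null(fixed_h)) check_scalar(fixed_h, "run.fixed_h")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 estimate_brightness = isTRUE(estimate_brightness),
                 background = background, fixed_h = fixed_h,
                 n_birth = as.integer(n_birth)),
            class = "run_config")
}

#' Validate a full configuration
#'
#' Checks all type invariants of the camera, optics and timing (and optional
#' model/run settings) and returns a single configuration object with derived
#' quantities attached: pixel area (nm^2) and the nominal diffraction limit
#' `0.61 * wavelength / na` (nm).
#'
#' @param camera A [camera_model()].
#' @param optics An [optics_model()].
#' @param timing An [acquisition_timing()].
#' @param model A [model_config()].
#' @param run A [run_config()].
#' @return An object of class `jt_config` with elements `camera`, `optics`,
#'   `timing`, `model`, `run`, `pixel_area`, `diffraction_limit`.
#' @examples
#' cfg <- validate_config(
#'   camera_model(100, 25, 10, 2, 133, 16, 16),
#'   optics_model(na = 1.49, wavelength = 565),
#'   acquisition_timing(n_frames = 22, exposure = 0.1))
#' cfg$diffraction_limit  # ~231 nm
#' @export
validate_config <- function(camera, optics, timing,
                            model = model_config(), run = run_config()) {
  if (!inherits(camera, "camera_model"))
    stop_field("camera", "must be a camera_model")
  if (!inherits(optics, "optics_model"))
    stop_field("optics", "must be an optics_model")
  if (!inherits(timing, "acq_timing"))
    stop_field("timing", "must be an acquisition timing")
  if (!inherits(model, "model_config"))
    stop_field("model", "must be a model_config")
  if (!inherits(run, "run_config"))
    stop_field("run", "must be a run_config")
  if (is.null(model$z_max)) model$z_max <- 2 * optics$dz
  if (is.null(model$d_ref))
    model$d_ref <- model$d_scale / max(model$d_shape - 1, 0.5)
  structure(list(camera = camera, optics = optics, timing = timing,
                 model = model, run = run,
                 pixel_area = pixel_area(camera),
                 diffraction_limit = diffraction_limit(optics)),
            class = "jt_config")
}

#' @export
print.jt_config <- function(x, ...) {
  cat(sprintf("<jt_config> %d frames, %d x %d px @ %g nm; diffraction limit %.1f nm; M = %d, K = %d\n",
              x$timing$n_frames, x$camera$n_rows, x$camera$n_cols,
              x$camera$pixel_size, x$diffraction_limit,
              x$model$M, x$model$K))
  invisible(x)
}
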