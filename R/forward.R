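# Forward model: system state -> expected photons per pixel -> camera counts.

#' Defocus-dependent lateral PSF width
#'
#' Width of the Gaussian PSF of an emitter at axial distance `z` from the
#' focal plane: `sigma(z) = sigma0 * sqrt(1 + (z / dz)^2)`.  The width is
#' even in `z` (the sign of the axial position is not identifiable from a
#' single 2D image plane), equals `sigma0` in focus and grows monotonically
#' with `|z|`.
#'
#' @param z Axial position(s), nm (vectorized).
#' @param optics An [optics_model()].
#' @return PSF width(s), nm.
#' @export
psf_lateral_width <- function(z, optics) {
  stopifnot(inherits(optics, "optics_model"))
  optics$sigma0 * sqrt(1 + (z / optics$dz)^2)
}

# Expected photons per pixel (full frame, P-vector in row-major pixel order)
# contributed by one emitter during one exposure, per unit of h * dt:
# (1/K) * sum_k [Phi-differences along x] (x) [Phi-differences along y].
unit_frame_contrib <- function(xs, ys, zs, camera, optics) {
  K <- length(xs)
  s <- psf_lateral_width(zs, optics)
  nc <- camera$n_cols; nr <- camera$n_rows
  xe <- (0:nc) * camera$pixel_size
  ye <- (0:nr) * camera$pixel_size
  Ax <- stats::pnorm((rep(xe, each = K) - xs) / s)
  dim(Ax) <- c(K, nc + 1L)
  Ay <- stats::pnorm((rep(ye, each = K) - ys) / s)
  dim(Ay) <- c(K, nr + 1L)
  px <- Ax[, -1L, drop = FALSE] - Ax[, -(nc + 1L), drop = FALSE]
  py <- Ay[, -1L, drop = FALSE] - Ay[, -(nr + 1L), drop = FALSE]
  # crossprod(px, py) is n_cols x n_rows; its column-major flattening is the
  # row-major pixel order p = (r - 1) * n_cols + c
  as.vector(crossprod(px, py)) / K
}

#' Expected photons from one emitter at one pixel
#'
#' Pixel-integrated Gaussian PSF with motion blur: the exposure-time integral
#' of the emitter's photon flux over the pixel region is approximated by `K`
#' sub-exposure (midpoint-in-time) positions, and at each the unit-mass 2D
#' Gaussian is integrated over the pixel in closed form via differences of
#' the Gaussian cumulative integral along each axis.
#'
#' @param positions `K x 3` matrix (or length-3 vector) of sub-exposure
#'   positions `(x, y, z)` in nm for one emitter during one frame.
#' @param brightness Emitter brightness `h`, photons/s (> 0).
#' @param p Pixel index (row-major; vectorized).
#' @param camera A [camera_model()].
#' @param optics An [optics_model()].
#' @param dt Exposure duration of the frame, seconds.
#' @return Expected photon count(s) at pixel(s) `p`.
#' @export
emitter_pixel_photons <- function(positions, brightness, p, camera, optics, dt) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  stopifnot(ncol(positions) == 3)
  if (!is.numeric(brightness) || brightness <= 0)
    stop("brightness must be > 0", call. = FALSE)
  p <- as.integer(p)
  if (any(p < 1L | p > n_pixels(camera)))
    stop(sprintf("pixel index out of range 1..%d", n_pixels(camera)), call. = FALSE)
  contrib <- unit_frame_contrib(positions[, 1], positions[, 2], positions[, 3],
                                camera, optics)
  brightness * dt * contrib[p]
}

#' Expected image of a system state
#'
#' Deterministic map from a [system_state()] to the expected photon count
#' `u[p, n]` at every pixel and frame: a spatially uniform, per-frame
#' background `F_n * pixel_area * dt_n` plus the pixel-integrated,
#' motion-blurred PSF contribution `h_n * dt_n * (...)` of every active
#' emitter (loads `b^m = 1`).  Expected counts are exactly additive across
#' active emitters.
#'
#' @param state A [system_state()].
#' @param config A [validate_config()] configuration.
#' @param decompose If `TRUE`, attach the background matrix and the list of
#'   per-emitter contribution matrices.
#' @return Object of class `expected_image`: list with `u` (`P x N` matrix,
#'   row-major pixel order) and, if requested, `background` and
#'   `per_emitter`.
#' @export
expected_image <- function(state, config, decompose = FALSE) {
  stopifnot(inherits(state, "system_state"), inherits(config, "jt_config"))
  cam <- config$camera
  N <- config$timing$n_frames
  dt <- exposure_durations(config$timing)
  P <- n_pixels(cam)
  Fn <- rep_len(state$F, N)
  bg <- matrix(rep(Fn * pixel_area(cam) * dt, each = P), nrow = P)
  u <- bg
  per <- if (decompose) vector("list", state$M) else NULL
  active <- which(state$b == 1L)
  hn <- rep_len(state$h, N)
  for (m in active) {
    cm <- emitter_stack_contrib(state, m, config)
    um <- sweep(cm, 2, hn * dt, "*")
    u <- u + um
    if (decompose) per[[m]] <- um
  }
  out <- list(u = u, n_frames = N)
  if (decompose) {
    out$background <- bg
    out$per_emitter <- per
  }
  structure(out, class = "expected_image")
}

# P x N matrix of unit (per h*dt) contributions of model emitter m.
emitter_stack_contrib <- function(state, m, config, frames = NULL) {
  K <- config$model$K
  N <- config$timing$n_frames
  if (is.null(frames)) frames <- seq_len(N)
  out <- matrix(0, n_pixels(config$camera), length(frames))
  for (j in seq_along(frames)) {
    n <- frames[j]
    idx <- ((n - 1L) * K + 1L):(n * K)
    out[, j] <- unit_frame_contrib(state$x[m, idx], state$y[m, idx],
                                   state$z[m, idx], config$camera, config$optics)
  }
  out
}

as_u_matrix <- function(u) {
  if (inherits(u, "expected_image")) u$u else as.matrix(u)
}

#' Sample camera counts for an expected image
#'
#' Draws the stochastic EMCCD read-out for every pixel and frame:
#' `w ~ Normal(offset + gain * u, read_variance + excess_noise * gain^2 * u)`,
#' independently across pixels and frames.
#'
#' @param u An [expected_image()] or nonnegative `P x N` matrix of expected
#'   photons.
#' @param camera A [camera_model()].
#' @param timing An [acquisition_timing()] (attached to the returned stack).
#' @param seed Optional integer seed for reproducible draws.
#' @return An [image_stack()].
#' @export
camera_sample <- function(u, camera, timing, seed = NULL) {
  um <- as_u_matrix(u)
  if (any(um < 0)) stop("expected photon counts must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mean_w <- camera$offset + camera$gain * um
  var_w <- camera$read_variance + camera$excess_noise * camera$gain^2 * um
  w <- matrix(stats::rnorm(length(um), mean_w, sqrt(var_w)), nrow = nrow(um))
  image_stack(matrix_to_frames(w, camera), timing, camera)
}

# vectorized normal log density sum over a matrix/vector
normal_loglik_sum <- function(w, u, camera) {
  v <- camera$read_variance + camera$excess_noise * camera$gain^2 * u
  r <- w - (camera$offset + camera$gain * u)
  -0.5 * sum(log(2 * pi * v) + r * r / v)
}

#' Log likelihood of an image stack
#'
#' Sum over all pixels and frames of the Gaussian EMCCD read-out log density
#' at the expected image.
#'
#' @param w An [image_stack()] (or `P x N` matrix of counts).
#' @param u An [expected_image()] (or `P x N` matrix of expected photons).
#' @param camera A [camera_model()]; taken from `w` when omitted.
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(w, u, camera = NULL) {
  if (inherits(w, "image_stack")) {
    if (is.null(camera)) camera <- w$camera
    w <- stack_matrix(w)
  } else {
    w <- as.matrix(w)
    if (is.null(camera)) stop("`camera` is required when `w` is a matrix", call. = FALSE)
  }
  um <- as_u_matrix(u)
  if (!all(dim(w) == dim(um)))
    stop(sprintf("shape mismatch: data %d x %d vs expectation %d x %d",
                 nrow(w), ncol(w), nrow(um), ncol(um)), call. = FALSE)
  normal_loglik_sum(w, um, camera)
}

# ---- system state -----------------------------------------------------------

#' System state of the generative model
#'
#' Gathers every unknown of the posterior: binary loads `b^m` (which of the
#' `M` model emitters are active), the model emitters' sub-exposure tracks,
#' the shared diffusion coefficient, per-frame brightness and per-frame
#' background photon flux.
#'
#' @param b Integer vector of length `M` with entries 0/1.
#' @param x,y,z `M x (K * n_frames)` matrices of sub-exposure positions, nm.
#' @param D Diffusion coefficient, nm^2/s (> 0).
#' @param h Per-frame emitter brightness, photons/s (length `n_frames` or 1).
#' @param F Per-frame background photon flux, photons/(nm^2 s)
#'   (length `n_frames` or 1, >= 0).
#' @return An object of class `system_state`.
#' @export
system_state <- function(b, x, y, z, D, h, F) {
  b <- as.integer(b)
  if (any(!b %in% c(0L, 1L))) stop("loads b must be 0 or 1", call. = FALSE)
  M <- length(b)
  for (nm in c("x", "y", "z")) {
    v <- get(nm)
    if (!is.matrix(v) || nrow(v) != M)
      stop(sprintf("`%s` must be an M x (K*N) matrix", nm), call. = FALSE)
    if (any(!is.finite(v)))
      stop(sprintf("`%s` must be finite", nm), call. = FALSE)
  }
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("diffusion coefficient D must be > 0", call. = FALSE)
  if (any(h <= 0)) stop("brightness h must be > 0", call. = FALSE)
  if (any(F < 0)) stop("background flux F must be >= 0", call. = FALSE)
  structure(list(b = b, x = x, y = y, z = z, D = D,
                 h = as.numeric(h), F = as.numeric(F), M = M),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> M = %d model emitters, B = %d active; D = %.3g nm^2/s\n",
              x$M, sum(x$b), x$D))
  invisible(x)
}

#' Number of active emitters of a state
#' @param state A [system_state()].
#' @return Integer `B = sum(b)`.
#' @export
active_count <- function(state) sum(state$b)

#' Frame-level track set of a state
#'
#' Collapses the sub-exposure tracks of the active emitters to one position
#' per frame (the within-exposure time average, the natural point estimate
#' under motion blur) and returns them as a [track_set()].
#'
#' @param state A [system_state()].
#' @param config A [validate_config()] configuration.
#' @param which_m Model emitter indices to export (default: active ones).
#' @return A [track_set()] with `z` holding signed axial positions.
#' @export
state_tracks <- function(state, config, which_m = which(state$b == 1L)) {
  K <- config$model$K
  N <- config$timing$n_frames
  if (!length(which_m)) stop("state has no active emitters", call. = FALSE)
  grp <- rep(seq_len(N), each = K)
  rows <- do.call(rbind, lapply(which_m, function(m) {
    data.frame(track = paste0("m", m), frame = seq_len(N),
               x = as.numeric(tapply(state$x[m, ], grp, mean)),
               y = as.numeric(tapply(state$y[m, ], grp, mean)),
               z = as.numeric(tapply(state$z[m, ], grp, mean)),
               present = TRUE)
  }))
  track_set(rows, n_frames = N)
}
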