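# Prior components of the joint posterior over loads, tracks and parameters.

#' Log prior of the loads vector
#'
#' Truncated Beta-Bernoulli prior on the binary loads: each of the `M` model
#' emitters is active independently with probability `gamma / M`, so the
#' expected number of active emitters is `gamma` at every truncation level
#' and the prior predictive of the active count converges to Poisson(gamma)
#' as `M` grows (the formal infinite limit of the latent-feature
#' construction).
#'
#' @param b Integer 0/1 vector of length `M`.
#' @param M Truncation level.
#' @param gamma Expected number of active emitters, `0 < gamma < M`.
#' @return Scalar log prior probability.
#' @export
loads_log_prior <- function(b, M = length(b), gamma) {
  b <- as.integer(b)
  if (any(!b %in% c(0L, 1L))) stop("loads b must be 0 or 1", call. = FALSE)
  if (length(b) != M) stop("length(b) must equal M", call. = FALSE)
  if (gamma <= 0 || gamma >= M)
    stop("gamma must satisfy 0 < gamma < M", call. = FALSE)
  q <- gamma / M
  s <- sum(b)
  s * log(q) + (M - s) * log1p(-q)
}

# support of the uniform initial-position density
initial_support <- function(config) {
  fs <- unname(fov_size(config$camera))
  margin <- config$model$fov_margin_px * config$camera$pixel_size
  list(x = c(-margin, fs[1] + margin),
       y = c(-margin, fs[2] + margin),
       z = c(-config$model$z_max, config$model$z_max))
}

initial_log_density <- function(x0, y0, z0, config) {
  s <- initial_support(config)
  inside <- x0 >= s$x[1] & x0 <= s$x[2] &
    y0 >= s$y[1] & y0 <= s$y[2] &
    z0 >= s$z[1] & z0 <= s$z[2]
  ld <- -log(diff(s$x)) - log(diff(s$y)) - log(diff(s$z))
  ifelse(inside, ld, -Inf)
}

#' Log probability of one track under the motion prior
#'
#' Brownian (normal diffusion) motion prior at sub-exposure resolution: the
#' initial position is uniform over the field of view expanded by a margin
#' (emitters may sit outside the FOV) with `z` uniform on
#' `[-z_max, z_max]`; each subsequent step is an independent
#' `Normal(0, 2 * D * dt)` increment per coordinate, with `dt` the (possibly
#' uneven) time between consecutive sub-exposure points, including dead time
#' between frames.
#'
#' @param track `S x 3` matrix of sub-exposure positions (columns x, y, z,
#'   nm), `S = K * n_frames`.
#' @param D Diffusion coefficient, nm^2/s (> 0).
#' @param config A [validate_config()] configuration.
#' @return Scalar log density.
#' @export
motion_log_prob <- function(track, D, config) {
  if (!is.numeric(D) || D <= 0) stop("D must be > 0", call. = FALSE)
  track <- as.matrix(track)
  if (any(!is.finite(track))) stop("track positions must be finite", call. = FALSE)
  grid <- subexposure_times(config$timing, config$model$K)
  if (nrow(track) != length(grid$times))
    stop("track must have K * n_frames rows", call. = FALSE)
  lp <- initial_log_density(track[1, 1], track[1, 2], track[1, 3], config)
  if (nrow(track) > 1L) {
    sd_step <- sqrt(2 * D * grid$dt)
    for (j in 1:3)
      lp <- lp + sum(stats::dnorm(diff(track[, j]), 0, sd_step, log = TRUE))
  }
  lp
}

#' Log prior of the scalar and per-frame parameters
#'
#' Independent priors: Inverse-Gamma(`d_shape`, scale `d_scale`) on the
#' diffusion coefficient (conjugate to the Gaussian increments of the motion
#' prior), and Gamma(shape, scale) priors on each frame's brightness `h_n`
#' and background flux `F_n`.  Brightness and background are a priori
#' independent across frames; both can vary substantially over an
#' acquisition.
#'
#' @param D Diffusion coefficient, nm^2/s.
#' @param h Brightness values, photons/s (any length).
#' @param F Background flux values, photons/(nm^2 s) (any length).
#' @param model A [model_config()] holding the hyperparameters.
#' @return Scalar log prior density.
#' @export
params_log_prior <- function(D, h, F, model) {
  stopifnot(inherits(model, "model_config"))
  if (any(D <= 0) || any(h <= 0) || any(F < 0))
    stop("require D > 0, h > 0, F >= 0", call. = FALSE)
  dinvgamma_log(D, model$d_shape, model$d_scale) +
    sum(stats::dgamma(h, shape = model$h_shape, scale = model$h_scale, log = TRUE)) +
    sum(stats::dgamma(F, shape = model$f_shape, scale = model$f_scale, log = TRUE))
}

dinvgamma_log <- function(x, shape, scale) {
  if (shape <= 0 || scale <= 0) stop("invalid Inverse-Gamma hyperparameters", call. = FALSE)
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

rinvgamma <- function(n, shape, scale) 1 / stats::rgamma(n, shape = shape, rate = scale)

#' Unnormalized log posterior of a system state
#'
#' Sum of the image log likelihood, the loads log prior, the motion log prior
#' of every model emitter's track, and the parameter log priors.  Active
#' emitters' tracks carry the motion prior at the shared diffusion
#' coefficient `D`; inactive emitters' tracks remain well-defined (so load
#' flips are dimension-preserving) and carry the motion prior at the fixed
#' reference diffusion `d_ref`, which leaves the marginal posterior over the
#' active configuration unchanged while decoupling `D` from prior-simulated
#' tracks.
#'
#' @param state A [system_state()].
#' @param data An [image_stack()] (may be `NULL` when
#'   `include_likelihood = FALSE`).
#' @param config A [validate_config()] configuration.
#' @param include_likelihood If `FALSE`, return the log prior only (used for
#'   sampler validation against the prior).
#' @return Scalar unnormalized log posterior.
#' @export
state_log_posterior <- function(state, data, config, include_likelihood = TRUE) {
  stopifnot(inherits(state, "system_state"), inherits(config, "jt_config"))
  lp <- loads_log_prior(state$b, state$M, config$model$gamma)
  for (m in seq_len(state$M)) {
    Dm <- if (state$b[m] == 1L) state$D else config$model$d_ref
    lp <- lp + motion_log_prob(cbind(state$x[m, ], state$y[m, ], state$z[m, ]),
                               Dm, config)
  }
  lp <- lp + params_log_prior(state$D, state$h, state$F, config$model)
  if (include_likelihood) {
    if (is.null(data)) stop("`data` required when include_likelihood = TRUE", call. = FALSE)
    lp <- lp + log_likelihood(data, expected_image(state, config))
  }
  lp
}
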