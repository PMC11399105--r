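# MCMC over the joint posterior: blocked Metropolis-Hastings track updates
# with Brownian-bridge proposals, birth/death load flips, conjugate diffusion
# updates and log-scale random walks on per-frame brightness and background.

# per-column (per-frame) log likelihood
loglik_cols <- function(w, u, camera) {
  v <- camera$read_variance + camera$excess_noise * camera$gain^2 * u
  r <- w - (camera$offset + camera$gain * u)
  -0.5 * colSums(log(2 * pi * v) + r * r / v)
}

# ---- sampler environment ----------------------------------------------------

make_sampler_env <- function(data, config, prior_only = FALSE) {
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$prior_only <- isTRUE(prior_only)
  e$grid <- subexposure_times(config$timing, config$model$K)
  e$N <- config$timing$n_frames
  e$P <- n_pixels(config$camera)
  e$K <- config$model$K
  e$dt <- exposure_durations(config$timing)
  e$area <- pixel_area(config$camera)
  e$w <- if (!is.null(data)) stack_matrix(data) else NULL
  sup <- initial_support(config)
  e$support <- sup
  e$log_unif_xy <- -log(diff(sup$x)) - log(diff(sup$y))
  e$acc <- list()
  if (!is.null(e$w)) {
    # data-informed birth proposal: mixture of the uniform prior and
    # Gaussians centred on above-median pixels, weighted by excess intensity
    wbar <- rowMeans(e$w)
    excess <- pmax(wbar - stats::median(wbar), 0)
    reg <- pixel_region(seq_len(e$P), config$camera)
    e$hot_cx <- (reg[, "x_min"] + reg[, "x_max"]) / 2
    e$hot_cy <- (reg[, "y_min"] + reg[, "y_max"]) / 2
    e$hot_w <- if (sum(excess) > 0) excess / sum(excess) else NULL
    e$hot_sd <- config$camera$pixel_size
  } else {
    e$hot_w <- NULL
  }
  e
}

# sample() on a length-one vector would sample from 1:x
sample_safe <- function(x, n = length(x)) x[sample.int(length(x), n)]

count_acc <- function(e, move, accepted) {
  cur <- e$acc[[move]]
  if (is.null(cur)) cur <- c(0, 0)
  e$acc[[move]] <- cur + c(as.numeric(accepted), 1)
}

# log density of the birth proposal for a lateral starting position
log_q0_xy <- function(e, x0, y0) {
  sup <- e$support
  inside <- x0 >= sup$x[1] && x0 <= sup$x[2] && y0 >= sup$y[1] && y0 <= sup$y[2]
  u_dens <- if (inside) exp(e$log_unif_xy) else 0
  if (is.null(e$hot_w)) return(if (inside) e$log_unif_xy else -Inf)
  g <- sum(e$hot_w * stats::dnorm(x0, e$hot_cx, e$hot_sd) *
             stats::dnorm(y0, e$hot_cy, e$hot_sd))
  log(0.5 * u_dens + 0.5 * g)
}

sample_q0_xy <- function(e) {
  sup <- e$support
  if (is.null(e$hot_w) || stats::runif(1) < 0.5) {
    c(stats::runif(1, sup$x[1], sup$x[2]), stats::runif(1, sup$y[1], sup$y[2]))
  } else {
    p <- sample.int(e$P, 1, prob = e$hot_w)
    c(stats::rnorm(1, e$hot_cx[p], e$hot_sd), stats::rnorm(1, e$hot_cy[p], e$hot_sd))
  }
}

# sample a full track from the motion prior at diffusion Dm
sample_prior_track <- function(e, Dm, start = NULL) {
  sup <- e$support
  S <- length(e$grid$times)
  if (is.null(start))
    start <- c(stats::runif(1, sup$x[1], sup$x[2]),
               stats::runif(1, sup$y[1], sup$y[2]),
               stats::runif(1, sup$z[1], sup$z[2]))
  sd_step <- sqrt(2 * Dm * e$grid$dt)
  inc <- matrix(stats::rnorm(3 * (S - 1)), ncol = 3) * sd_step
  rbind(start, sweep(apply(inc, 2, cumsum), 2, start, "+"), deparse.level = 0)
}

set_state <- function(e, state) {
  stopifnot(inherits(state, "system_state"))
  e$b <- state$b; e$x <- state$x; e$y <- state$y; e$z <- state$z
  e$D <- state$D
  e$h <- rep_len(state$h, e$N)
  e$Fn <- rep_len(state$F, e$N)
  e$M <- state$M
  e$contrib <- vector("list", e$M)
  if (!e$prior_only)
    for (m in which(e$b == 1L))
      e$contrib[[m]] <- emitter_stack_contrib(state, m, e$config)
  rebuild_cache(e)
}

rebuild_cache <- function(e) {
  if (e$prior_only || is.null(e$w)) {
    e$llf <- numeric(e$N)
    return(invisible())
  }
  act <- which(e$b == 1L)
  e$csum <- if (length(act)) Reduce(`+`, e$contrib[act]) else matrix(0, e$P, e$N)
  e$bg <- matrix(rep(e$Fn * e$area * e$dt, each = e$P), nrow = e$P)
  e$u <- e$bg + e$csum * rep(e$h * e$dt, each = e$P)
  e$llf <- loglik_cols(e$w, e$u, e$config$camera)
}

get_state <- function(e) {
  system_state(b = e$b, x = e$x, y = e$y, z = e$z, D = e$D, h = e$h, F = e$Fn)
}

# unnormalized log posterior of the cached state (prior part recomputed
# through the same functions as state_log_posterior)
env_log_posterior <- function(e) {
  cfg <- e$config
  lp <- loads_log_prior(e$b, e$M, cfg$model$gamma)
  for (m in seq_len(e$M)) {
    Dm <- if (e$b[m] == 1L) e$D else cfg$model$d_ref
    lp <- lp + motion_log_prob(cbind(e$x[m, ], e$y[m, ], e$z[m, ]), Dm, cfg)
  }
  lp <- lp + params_log_prior(e$D, e$h, e$Fn, cfg$model)
  if (!e$prior_only) lp <- lp + sum(e$llf)
  lp
}

# delta log likelihood of replacing emitter m's contribution on `frames`
delta_ll_contrib <- function(e, frames, new_cols, old_cols) {
  if (e$prior_only) return(0)
  scale <- rep(e$h[frames] * e$dt[frames], each = e$P)
  u_new <- e$u[, frames, drop = FALSE] + (new_cols - old_cols) * scale
  ll_new <- loglik_cols(e$w[, frames, drop = FALSE], u_new, e$config$camera)
  list(dll = sum(ll_new) - sum(e$llf[frames]), u_new = u_new, ll_new = ll_new)
}

apply_contrib <- function(e, m, frames, new_cols, du) {
  old <- e$contrib[[m]][, frames, drop = FALSE]
  e$contrib[[m]][, frames] <- new_cols
  e$csum[, frames] <- e$csum[, frames] - old + new_cols
  if (!e$prior_only) {
    e$u[, frames] <- du$u_new
    e$llf[frames] <- du$ll_new
  }
}

# ---- track updates ----------------------------------------------------------

# Brownian-bridge proposal for the sub-exposure points of frames a..b of
# emitter m, conditioned on the neighbouring fixed points.  The proposal is
# the motion prior conditioned on the anchors, so prior and proposal cancel
# in the MH ratio up to the initial-position density when the block includes
# the track start.
propose_block <- function(e, m, a, b) {
  K <- e$K
  i0 <- (a - 1L) * K + 1L
  i1 <- b * K
  S <- length(e$grid$times)
  tms <- e$grid$times
  idx <- i0:i1
  D <- if (e$b[m] == 1L) e$D else e$config$model$d_ref
  cur <- cbind(e$x[m, ], e$y[m, ], e$z[m, ])
  newp <- matrix(NA_real_, length(idx), 3)
  has_left <- i0 > 1L
  has_right <- i1 < S

  if (has_left && has_right) {
    prev_t <- tms[i0 - 1L]; prev <- cur[i0 - 1L, ]
    rt <- tms[i1 + 1L]; rv <- cur[i1 + 1L, ]
    for (j in seq_along(idx)) {
      tj <- tms[idx[j]]
      frac <- (tj - prev_t) / (rt - prev_t)
      mu <- prev + (rv - prev) * frac
      v <- 2 * D * (tj - prev_t) * (rt - tj) / (rt - prev_t)
      newp[j, ] <- stats::rnorm(3, mu, sqrt(v))
      prev <- newp[j, ]; prev_t <- tj
    }
  } else if (has_left) {
    prev_t <- tms[i0 - 1L]; prev <- cur[i0 - 1L, ]
    for (j in seq_along(idx)) {
      tj <- tms[idx[j]]
      newp[j, ] <- stats::rnorm(3, prev, sqrt(2 * D * (tj - prev_t)))
      prev <- newp[j, ]; prev_t <- tj
    }
  } else if (has_right) {
    nxt_t <- tms[i1 + 1L]; nxt <- cur[i1 + 1L, ]
    for (j in rev(seq_along(idx))) {
      tj <- tms[idx[j]]
      newp[j, ] <- stats::rnorm(3, nxt, sqrt(2 * D * (nxt_t - tj)))
      nxt <- newp[j, ]; nxt_t <- tj
    }
  } else {
    newp <- sample_prior_track(e, D)
  }
  newp
}

update_tracks <- function(e, wlen) {
  N <- e$N; K <- e$K
  for (m in which(e$b == 1L)) {
    phase <- sample.int(wlen, 1) - 1L
    starts <- unique(pmax(1L, seq(1L - phase, N, by = wlen)))
    for (a in starts) {
      b2 <- min(a + wlen - 1L, N)
      newp <- propose_block(e, m, a, b2)
      frames <- a:b2
      idx <- ((a - 1L) * K + 1L):(b2 * K)
      log_r <- 0
      if (a == 1L) {
        # block contains the track start: initial-density ratio survives
        new_init <- initial_log_density(newp[1, 1], newp[1, 2], newp[1, 3], e$config)
        old_init <- initial_log_density(e$x[m, 1], e$y[m, 1], e$z[m, 1], e$config)
        log_r <- log_r + new_init - old_init
      }
      if (!is.finite(log_r)) { count_acc(e, "track", FALSE); next }
      if (e$prior_only) {
        ok <- log(stats::runif(1)) < log_r
        if (ok) {
          e$x[m, idx] <- newp[, 1]; e$y[m, idx] <- newp[, 2]; e$z[m, idx] <- newp[, 3]
        }
        count_acc(e, "track", ok)
        next
      }
      xs <- e$x[m, ]; ys <- e$y[m, ]; zs <- e$z[m, ]
      xs[idx] <- newp[, 1]; ys[idx] <- newp[, 2]; zs[idx] <- newp[, 3]
      new_cols <- frames_contrib(e, xs, ys, zs, frames)
      du <- delta_ll_contrib(e, frames, new_cols, e$contrib[[m]][, frames, drop = FALSE])
      log_r <- log_r + du$dll
      ok <- log(stats::runif(1)) < log_r
      if (ok) {
        e$x[m, idx] <- newp[, 1]; e$y[m, idx] <- newp[, 2]; e$z[m, idx] <- newp[, 3]
        apply_contrib(e, m, frames, new_cols, du)
      }
      count_acc(e, "track", ok)
    }
  }
}

# Whole-track translation: symmetric Gaussian shift of an active emitter's
# entire track (the motion prior is translation invariant, so only the
# likelihood and the initial-position density enter the ratio).  Repairs
# whole-track offsets that per-window bridge moves fix only diffusively.
update_translations <- function(e, sd_xy = 25, sd_z = 50) {
  for (m in which(e$b == 1L)) {
    dx <- stats::rnorm(1, 0, sd_xy); dy <- stats::rnorm(1, 0, sd_xy)
    dz <- stats::rnorm(1, 0, sd_z)
    xs <- e$x[m, ] + dx; ys <- e$y[m, ] + dy; zs <- e$z[m, ] + dz
    log_r <- initial_log_density(xs[1], ys[1], zs[1], e$config) -
      initial_log_density(e$x[m, 1], e$y[m, 1], e$z[m, 1], e$config)
    if (!is.finite(log_r)) { count_acc(e, "translate", FALSE); next }
    if (!e$prior_only) {
      new_cols <- frames_contrib(e, xs, ys, zs, seq_len(e$N))
      du <- delta_ll_contrib(e, seq_len(e$N), new_cols, e$contrib[[m]])
      log_r <- log_r + du$dll
    }
    ok <- log(stats::runif(1)) < log_r
    if (ok) {
      e$x[m, ] <- xs; e$y[m, ] <- ys; e$z[m, ] <- zs
      if (!e$prior_only) apply_contrib(e, m, seq_len(e$N), new_cols, du)
    }
    count_acc(e, "translate", ok)
  }
}

frames_contrib <- function(e, xs, ys, zs, frames) {
  K <- e$K
  out <- matrix(0, e$P, length(frames))
  for (j in seq_along(frames)) {
    n <- frames[j]
    idx <- ((n - 1L) * K + 1L):(n * K)
    out[, j] <- unit_frame_contrib(xs[idx], ys[idx], zs[idx],
                                   e$config$camera, e$config$optics)
  }
  out
}

refresh_inactive <- function(e) {
  for (m in which(e$b == 0L)) {
    p <- sample_prior_track(e, e$config$model$d_ref)
    e$x[m, ] <- p[, 1]; e$y[m, ] <- p[, 2]; e$z[m, ] <- p[, 3]
  }
}

# ---- load (birth / death) moves ---------------------------------------------

# Birth/death load flips.  A random subset of ALL M model emitters is
# selected each sweep and a flip is attempted on each: the selection
# probability is then identical for the forward and reverse move of any
# flip, so it cancels from the acceptance ratio (selecting actives and
# inactives at different rates would break detailed balance on the loads).
update_loads <- function(e) {
  q <- e$config$model$gamma / e$M
  log_odds <- log(q) - log1p(-q)
  n_try <- min(e$M, e$config$run$n_birth)
  for (m in sample_safe(seq_len(e$M), n_try)) {
    if (e$b[m] == 1L) {
      # death attempt; the replacement inactive track is drawn from the
      # reference-diffusion motion prior (its density cancels)
      log_r <- -log_odds + log_q0_xy(e, e$x[m, 1], e$y[m, 1]) - e$log_unif_xy
      if (!e$prior_only) {
        old_cols <- e$contrib[[m]]
        du <- delta_ll_contrib(e, seq_len(e$N), matrix(0, e$P, e$N), old_cols)
        log_r <- log_r + du$dll
      }
      ok <- log(stats::runif(1)) < log_r
      if (ok) {
        e$b[m] <- 0L
        if (!e$prior_only) {
          e$csum <- e$csum - old_cols
          e$contrib[m] <- list(NULL)
          e$u <- du$u_new; e$llf <- du$ll_new
        }
        p <- sample_prior_track(e, e$config$model$d_ref)
        e$x[m, ] <- p[, 1]; e$y[m, ] <- p[, 2]; e$z[m, ] <- p[, 3]
      }
      count_acc(e, "death", ok)
    } else {
      xy0 <- sample_q0_xy(e)
      z0 <- stats::runif(1, e$support$z[1], e$support$z[2])
      tau <- sample_prior_track(e, e$D, start = c(xy0, z0))
      lq <- log_q0_xy(e, xy0[1], xy0[2])
      log_r <- log_odds + e$log_unif_xy - lq
      # starting position must be inside the prior support
      if (!is.finite(initial_log_density(xy0[1], xy0[2], z0, e$config))) {
        count_acc(e, "birth", FALSE); next
      }
      if (!e$prior_only) {
        new_cols <- frames_contrib(e, tau[, 1], tau[, 2], tau[, 3], seq_len(e$N))
        du <- delta_ll_contrib(e, seq_len(e$N), new_cols, matrix(0, e$P, e$N))
        log_r <- log_r + du$dll
      }
      ok <- log(stats::runif(1)) < log_r
      if (ok) {
        e$b[m] <- 1L
        e$x[m, ] <- tau[, 1]; e$y[m, ] <- tau[, 2]; e$z[m, ] <- tau[, 3]
        if (!e$prior_only) {
          e$contrib[[m]] <- new_cols
          e$csum <- e$csum + new_cols
          e$u <- du$u_new; e$llf <- du$ll_new
        }
      }
      count_acc(e, "birth", ok)
    }
  }
}

# ---- parameter updates ------------------------------------------------------

#' Full conditional of the diffusion coefficient
#'
#' Inverse-Gamma full conditional of `D` given the active emitters'
#' sub-exposure track increments: shape `d_shape + n_increments / 2`, scale
#' `d_scale + sum(increment^2 / (4 dt))`.
#'
#' @param state A [system_state()].
#' @param config A [validate_config()] configuration.
#' @return List with `shape` and `scale`; draw via `1 / rgamma(n, shape,
#'   rate = scale)`.
#' @export
d_full_conditional <- function(state, config) {
  grid <- subexposure_times(config$timing, config$model$K)
  shape <- config$model$d_shape
  scale <- config$model$d_scale
  for (m in which(state$b == 1L)) {
    for (v in list(state$x[m, ], state$y[m, ], state$z[m, ])) {
      d <- diff(v)
      shape <- shape + length(d) / 2
      scale <- scale + sum(d^2 / (4 * grid$dt))
    }
  }
  list(shape = shape, scale = scale)
}

update_D <- function(e) {
  fc <- d_full_conditional(get_state_light(e), e$config)
  e$D <- rinvgamma(1, fc$shape, fc$scale)
  d_scaling_move(e)
  d_bridge_scaling_move(e)
  d_bridge_scaling_move(e)
}

# step sizes of the scaling move, cycled (small steps accept often, large
# steps cross scales)
d_scale_sds <- c(0.1, 0.2, 0.35)

# Joint (D, increments) scaling move: D' = c * D with all active tracks'
# increments rescaled by sqrt(c) about their starts, so the motion-prior
# terms cancel exactly; this decorrelates D from the prior-dominated
# sub-exposure increments.
d_scaling_move <- function(e) {
  cc <- exp(stats::rnorm(1, 0, sample(d_scale_sds, 1)))
  Dn <- e$D * cc
  act <- which(e$b == 1L)
  mc <- e$config$model
  log_r <- dinvgamma_log(Dn, mc$d_shape, mc$d_scale) -
    dinvgamma_log(e$D, mc$d_shape, mc$d_scale) + log(cc)
  if (length(act) == 0L || e$prior_only) {
    # no likelihood change (no active contribs maintained)
    newpos <- if (length(act)) rescale_tracks(e, act, cc) else NULL
    if (!is.null(newpos) && !starts_inside(e, newpos)) {
      count_acc(e, "d_scale", FALSE)
      return(invisible())
    }
    ok <- log(stats::runif(1)) < log_r
    if (ok) {
      e$D <- Dn
      if (!is.null(newpos)) set_positions(e, act, newpos)
    }
    count_acc(e, "d_scale", ok)
    return(invisible())
  }
  newpos <- rescale_tracks(e, act, cc)
  if (!starts_inside(e, newpos)) {
    count_acc(e, "d_scale", FALSE)
    return(invisible())
  }
  new_contribs <- lapply(seq_along(act), function(i) {
    frames_contrib(e, newpos$x[i, ], newpos$y[i, ], newpos$z[i, ], seq_len(e$N))
  })
  csum_new <- Reduce(`+`, new_contribs)
  u_new <- e$bg + csum_new * rep(e$h * e$dt, each = e$P)
  ll_new <- loglik_cols(e$w, u_new, e$config$camera)
  log_r <- log_r + sum(ll_new) - sum(e$llf)
  ok <- log(stats::runif(1)) < log_r
  if (ok) {
    e$D <- Dn
    set_positions(e, act, newpos)
    for (i in seq_along(act)) e$contrib[[act[i]]] <- new_contribs[[i]]
    e$csum <- csum_new; e$u <- u_new; e$llf <- ll_new
  }
  count_acc(e, "d_scale", ok)
}

# Non-centered (D, bridge-deviation) scaling move.  The sub-exposure points
# between consecutive frame anchors (the first sub-position of each frame)
# carry essentially no information about D: their full conditional is the
# Brownian bridge at the current D, so a centered sampler lets them
# pseudo-inform the D full conditional and the chain under-represents D's
# uncertainty (a funnel).  This move proposes D' = c * D while rescaling
# every track's bridge deviations about the time-linear interpolation
# between its fixed frame anchors by sqrt(c) (free-end tail rescaled about
# the last anchor).  The bridge densities and the Jacobian cancel exactly,
# leaving the D prior ratio, the anchor-increment prior ratio (the
# identifiable frame-scale information) and a mild likelihood ratio from
# the changed motion blur.
d_bridge_scaling_move <- function(e) {
  cc <- exp(stats::rnorm(1, 0, 0.25))
  Dn <- e$D * cc
  act <- which(e$b == 1L)
  mc <- e$config$model
  log_r <- dinvgamma_log(Dn, mc$d_shape, mc$d_scale) -
    dinvgamma_log(e$D, mc$d_shape, mc$d_scale) + log(cc)
  K <- e$K
  S <- length(e$grid$times)
  sk <- seq(1L, S, by = K)
  tms <- e$grid$times
  dts <- diff(tms[sk])
  resc <- function(v) {
    out <- v
    s <- sqrt(cc)
    for (n in seq_len(length(sk) - 1L)) {
      i0 <- sk[n]; i1 <- sk[n + 1L]
      if (i1 - i0 > 1L) {
        j <- (i0 + 1L):(i1 - 1L)
        interp <- v[i0] + (v[i1] - v[i0]) * (tms[j] - tms[i0]) / (tms[i1] - tms[i0])
        out[j] <- interp + s * (v[j] - interp)
      }
    }
    if (sk[length(sk)] < S) {
      j <- (sk[length(sk)] + 1L):S
      out[j] <- v[sk[length(sk)]] + s * (v[j] - v[sk[length(sk)]])
    }
    out
  }
  skel_ratio <- function(v) {
    d <- diff(v[sk])
    sum(stats::dnorm(d, 0, sqrt(2 * Dn * dts), log = TRUE) -
          stats::dnorm(d, 0, sqrt(2 * e$D * dts), log = TRUE))
  }
  if (length(act) == 0L || e$prior_only) {
    if (length(act)) {
      for (m in act) {
        log_r <- log_r + skel_ratio(e$x[m, ]) + skel_ratio(e$y[m, ]) +
          skel_ratio(e$z[m, ])
      }
    }
    ok <- log(stats::runif(1)) < log_r
    if (ok) {
      e$D <- Dn
      for (m in act) {
        e$x[m, ] <- resc(e$x[m, ]); e$y[m, ] <- resc(e$y[m, ])
        e$z[m, ] <- resc(e$z[m, ])
      }
    }
    count_acc(e, "d_bridge", ok)
    return(invisible())
  }
  newx <- lapply(act, function(m) resc(e$x[m, ]))
  newy <- lapply(act, function(m) resc(e$y[m, ]))
  newz <- lapply(act, function(m) resc(e$z[m, ]))
  for (i in seq_along(act)) {
    m <- act[i]
    log_r <- log_r + skel_ratio(e$x[m, ]) + skel_ratio(e$y[m, ]) +
      skel_ratio(e$z[m, ])
  }
  new_contribs <- lapply(seq_along(act), function(i)
    frames_contrib(e, newx[[i]], newy[[i]], newz[[i]], seq_len(e$N)))
  csum_new <- Reduce(`+`, new_contribs)
  u_new <- e$bg + csum_new * rep(e$h * e$dt, each = e$P)
  ll_new <- loglik_cols(e$w, u_new, e$config$camera)
  log_r <- log_r + sum(ll_new) - sum(e$llf)
  ok <- log(stats::runif(1)) < log_r
  if (ok) {
    e$D <- Dn
    for (i in seq_along(act)) {
      m <- act[i]
      e$x[m, ] <- newx[[i]]; e$y[m, ] <- newy[[i]]; e$z[m, ] <- newz[[i]]
      e$contrib[[m]] <- new_contribs[[i]]
    }
    e$csum <- csum_new; e$u <- u_new; e$llf <- ll_new
  }
  count_acc(e, "d_bridge", ok)
}

# Rescale increments by sqrt(cc) about each track's mean position: the
# Jacobian and motion-prior cancellation are the same as rescaling about the
# start (triangular map with block diag(1, sqrt(cc) I)), but frame positions
# move less, so the likelihood accepts larger D steps.
rescale_tracks <- function(e, act, cc) {
  s <- sqrt(cc)
  resc <- function(mat) {
    m0 <- rowMeans(mat)
    m0 + s * sweep(mat, 1, m0, "-")
  }
  list(x = resc(e$x[act, , drop = FALSE]),
       y = resc(e$y[act, , drop = FALSE]),
       z = resc(e$z[act, , drop = FALSE]))
}

# all rescaled track starts must stay inside the uniform prior support
starts_inside <- function(e, newpos) {
  all(is.finite(vapply(seq_len(nrow(newpos$x)), function(i)
    initial_log_density(newpos$x[i, 1], newpos$y[i, 1], newpos$z[i, 1],
                        e$config), numeric(1))))
}

set_positions <- function(e, act, newpos) {
  e$x[act, ] <- newpos$x; e$y[act, ] <- newpos$y; e$z[act, ] <- newpos$z
}

# light-weight state for d_full_conditional (no validation copies)
get_state_light <- function(e) {
  structure(list(b = e$b, x = e$x, y = e$y, z = e$z, D = e$D,
                 h = e$h, F = e$Fn, M = e$M), class = "system_state")
}

update_h <- function(e) {
  if (!e$config$run$estimate_brightness) return(invisible())
  mc <- e$config$model
  if (e$prior_only) {
    e$h <- stats::rgamma(e$N, shape = mc$h_shape, scale = mc$h_scale)
    return(invisible())
  }
  for (n in seq_len(e$N)) {
    hn <- e$h[n]
    hp <- hn * exp(stats::rnorm(1, 0, 0.1))
    u_new <- e$bg[, n] + e$csum[, n] * hp * e$dt[n]
    ll_new <- loglik_cols(e$w[, n, drop = FALSE], cbind(u_new), e$config$camera)
    log_r <- ll_new - e$llf[n] +
      stats::dgamma(hp, mc$h_shape, scale = mc$h_scale, log = TRUE) -
      stats::dgamma(hn, mc$h_shape, scale = mc$h_scale, log = TRUE) +
      log(hp) - log(hn)
    ok <- log(stats::runif(1)) < log_r
    if (ok) {
      e$h[n] <- hp
      e$u[, n] <- u_new
      e$llf[n] <- ll_new
    }
    count_acc(e, "h", ok)
  }
}

update_F <- function(e) {
  mc <- e$config$model
  constant <- identical(e$config$run$background, "constant")
  if (e$prior_only) {
    f <- stats::rgamma(if (constant) 1 else e$N, shape = mc$f_shape, scale = mc$f_scale)
    e$Fn <- rep_len(f, e$N)
    e$bg <- matrix(rep(e$Fn * e$area * e$dt, each = e$P), nrow = e$P)
    return(invisible())
  }
  if (constant) {
    f0 <- e$Fn[1]
    fp <- f0 * exp(stats::rnorm(1, 0, 0.05))
    bg_new <- matrix(rep(fp * e$area * e$dt, each = e$P), nrow = e$P)
    u_new <- bg_new + e$csum * rep(e$h * e$dt, each = e$P)
    ll_new <- loglik_cols(e$w, u_new, e$config$camera)
    log_r <- sum(ll_new) - sum(e$llf) +
      stats::dgamma(fp, mc$f_shape, scale = mc$f_scale, log = TRUE) -
      stats::dgamma(f0, mc$f_shape, scale = mc$f_scale, log = TRUE) +
      log(fp) - log(f0)
    ok <- log(stats::runif(1)) < log_r
    if (ok) {
      e$Fn <- rep(fp, e$N); e$bg <- bg_new; e$u <- u_new; e$llf <- ll_new
    }
    count_acc(e, "F", ok)
  } else {
    for (n in seq_len(e$N)) {
      f0 <- e$Fn[n]
      fp <- f0 * exp(stats::rnorm(1, 0, 0.05))
      bg_n <- fp * e$area * e$dt[n]
      u_new <- bg_n + e$csum[, n] * e$h[n] * e$dt[n]
      ll_new <- loglik_cols(e$w[, n, drop = FALSE], cbind(u_new), e$config$camera)
      log_r <- ll_new - e$llf[n] +
        stats::dgamma(fp, mc$f_shape, scale = mc$f_scale, log = TRUE) -
        stats::dgamma(f0, mc$f_shape, scale = mc$f_scale, log = TRUE) +
        log(fp) - log(f0)
      ok <- log(stats::runif(1)) < log_r
      if (ok) {
        e$Fn[n] <- fp
        e$bg[, n] <- bg_n
        e$u[, n] <- u_new
        e$llf[n] <- ll_new
      }
      count_acc(e, "F", ok)
    }
  }
}

# ---- public sampler operations ----------------------------------------------

window_schedule <- c(1L, 3L, 7L)

#' Initial system state
#'
#' Deterministic given the seed: all loads start inactive (emitters are
#' recruited during burn-in), the background flux is inverted from the
#' frame-wise lower-quartile pixel intensity through the camera model, the
#' brightness from the frame's excess counts (or `fixed_h`), and `D` from
#' its prior mean.
#'
#' @param data An [image_stack()].
#' @param config A [validate_config()] configuration.
#' @param seed Integer seed.
#' @return A [system_state()].
#' @export
init_state <- function(data, config, seed = config$run$seed) {
  stopifnot(inherits(config, "jt_config"))
  if (is.null(data) || prod(dim(data$values)) == 0)
    stop("empty image stack", call. = FALSE)
  set.seed(as.integer(seed))
  cam <- config$camera
  w <- stack_matrix(data)
  N <- config$timing$n_frames
  dt <- exposure_durations(config$timing)
  q25 <- apply(w, 2, stats::quantile, probs = 0.25, names = FALSE)
  u_bg <- pmax((q25 - cam$offset) / cam$gain, 1e-3)
  Fn <- u_bg / (pixel_area(cam) * dt)
  if (identical(config$run$background, "constant")) Fn <- rep(mean(Fn), N)
  hn <- if (!is.null(config$run$fixed_h)) {
    rep(config$run$fixed_h, N)
  } else {
    excess <- pmax(colSums(w) - nrow(w) * q25, 0) / cam$gain
    pmax(excess / dt, 100)
  }
  e <- make_sampler_env(data, config)
  M <- config$model$M
  S <- length(e$grid$times)
  x <- y <- z <- matrix(0, M, S)
  for (m in seq_len(M)) {
    p <- sample_prior_track(e, config$model$d_ref)
    x[m, ] <- p[, 1]; y[m, ] <- p[, 2]; z[m, ] <- p[, 3]
  }
  D0 <- config$model$d_scale / max(config$model$d_shape - 1, 0.5)
  system_state(b = rep(0L, M), x = x, y = y, z = z, D = D0, h = hn, F = Fn)
}

run_sweep <- function(e, it) {
  wlen <- window_schedule[(it - 1L) %% length(window_schedule) + 1L]
  update_tracks(e, wlen)
  update_translations(e)
  update_D(e)
  refresh_inactive(e)
  update_loads(e)
  update_D(e)
  update_h(e)
  update_F(e)
}

#' One full MCMC sweep
#'
#' Applies, in order: blocked track updates for active emitters (window
#' length cycling through 1, 3, 7 frames) with Brownian-bridge proposals;
#' exact refresh of inactive emitters' tracks from the motion prior;
#' birth/death load flips (birth tracks proposed with a data-informed
#' starting position whose density enters the acceptance ratio); a conjugate
#' Inverse-Gamma draw of `D` plus a joint (D, increments) scaling move; and
#' log-scale random-walk updates of per-frame brightness and background.
#' Every move satisfies detailed balance with respect to
#' [state_log_posterior()].
#'
#' @param state A [system_state()].
#' @param data An [image_stack()].
#' @param config A [validate_config()] configuration.
#' @param it Sweep index (selects the track-window length).
#' @return The updated [system_state()].
#' @export
sweep_state <- function(state, data, config, it = 1L) {
  e <- make_sampler_env(data, config)
  set_state(e, state)
  run_sweep(e, as.integer(it))
  get_state(e)
}

#' Run an MCMC chain
#'
#' Runs `run$iterations` sweeps from [init_state()], discards `run$burn_in`,
#' and retains every `run$thin`-th sample with its unnormalized log
#' posterior.  Fully reproducible given `run$seed`.
#'
#' @param data An [image_stack()].
#' @param config A [validate_config()] configuration (its `run` settings
#'   control iterations, burn-in, thinning and seed).
#' @param prior_only If `TRUE`, the likelihood term is disabled and the
#'   chain targets the prior (sampler-correctness validation).
#' @param init Optional initial [system_state()] (e.g. to resume a run).
#' @param progress Print a progress line every `progress` sweeps (0 = quiet).
#' @return An object of class `jt_chain`: list with `samples` (retained
#'   [system_state()]s), `log_post`, `B`, `D` (per retained sample), `trace`
#'   (per-sweep log posterior and active count), `acceptance` rates per move
#'   type, and the run bookkeeping.
#' @export
run_chain <- function(data, config, prior_only = FALSE, init = NULL,
                      progress = 0) {
  stopifnot(inherits(config, "jt_config"))
  run <- config$run
  set.seed(run$seed)
  state <- if (is.null(init)) {
    if (prior_only && is.null(data)) prior_init_state(config) else init_state(data, config, seed = run$seed)
  } else init
  e <- make_sampler_env(data, config, prior_only = prior_only)
  set_state(e, state)
  n_keep <- length(seq_len(run$iterations)[-seq_len(run$burn_in)])
  if (n_keep == 0L)
    warning("burn_in equals iterations: no samples retained", call. = FALSE)
  samples <- list()
  log_post <- numeric(0)
  trace_lp <- numeric(run$iterations)
  trace_B <- integer(run$iterations)
  for (it in seq_len(run$iterations)) {
    run_sweep(e, it)
    if (!e$prior_only && !all(is.finite(e$llf)))
      stop(sprintf("non-finite log-likelihood at sweep %d", it), call. = FALSE)
    trace_B[it] <- sum(e$b)
    keep <- it > run$burn_in && ((it - run$burn_in - 1L) %% run$thin == 0L)
    if (keep || it == run$iterations || progress > 0) {
      # exact cache rebuild kills float drift before recording
      rebuild_cache(e)
    }
    lp <- if (keep || progress > 0) env_log_posterior(e) else NA_real_
    trace_lp[it] <- lp
    if (keep) {
      if (!is.finite(lp))
        stop(sprintf("non-finite log posterior at sweep %d", it), call. = FALSE)
      samples[[length(samples) + 1L]] <- get_state(e)
      log_post <- c(log_post, lp)
    }
    if (progress > 0 && it %% progress == 0)
      message(sprintf("sweep %d/%d: log posterior %.1f, B = %d",
                      it, run$iterations, lp, sum(e$b)))
  }
  acc <- vapply(e$acc, function(v) if (v[2] > 0) v[1] / v[2] else NA_real_,
                numeric(1))
  structure(list(samples = samples, log_post = log_post,
                 B = vapply(samples, active_count, integer(1)),
                 D = vapply(samples, function(s) s$D, numeric(1)),
                 trace = data.frame(iteration = seq_len(run$iterations),
                                    log_post = trace_lp, B = trace_B),
                 acceptance = acc, seed = run$seed,
                 iterations = run$iterations, burn_in = run$burn_in,
                 thin = run$thin, prior_only = prior_only, config = config),
            class = "jt_chain")
}

# initial state for likelihood-free runs (no data to invert)
prior_init_state <- function(config) {
  e <- make_sampler_env(NULL, config)
  M <- config$model$M
  S <- length(e$grid$times)
  x <- y <- z <- matrix(0, M, S)
  for (m in seq_len(M)) {
    p <- sample_prior_track(e, config$model$d_ref)
    x[m, ] <- p[, 1]; y[m, ] <- p[, 2]; z[m, ] <- p[, 3]
  }
  system_state(b = rep(0L, M), x = x, y = y, z = z,
               D = config$model$d_scale / max(config$model$d_shape - 1, 0.5),
               h = rep(config$model$h_shape * config$model$h_scale, config$timing$n_frames),
               F = rep(config$model$f_shape * config$model$f_scale, config$timing$n_frames))
}

#' @export
print.jt_chain <- function(x, ...) {
  cat(sprintf("<jt_chain> %d retained samples (of %d sweeps, burn-in %d); B range %s\n",
              length(x$samples), x$iterations, x$burn_in,
              if (length(x$B)) paste(range(x$B), collapse = "-") else "NA"))
  if (length(x$acceptance))
    cat("acceptance:", paste(sprintf("%s %.2f", names(x$acceptance), x$acceptance),
                             collapse = ", "), "\n")
  invisible(x)
}

# ---- posterior summaries ----------------------------------------------------

#' Maximum a posteriori track estimate
#'
#' Two-stage rule: the reported emitter count `B_MAP` is the most frequent
#' active count among retained samples; the reported state is the
#' highest-log-posterior sample among those with `B = B_MAP` (ties broken by
#' first occurrence).  Per-frame, per-coordinate 95% credible intervals are
#' computed across samples by matching each sample's emitter positions to
#' the MAP tracks frame by frame (nearest-position assignment, no gate),
#' since emitter labels are arbitrary across samples.
#'
#' @param chain A [run_chain()] result.
#' @param ci Compute track credible intervals (requires >= 40 samples).
#' @return Object of class `track_estimate`: list with `B_map`, `state` (the
#'   MAP [system_state()]), `tracks` (frame-level [track_set()], `NULL` when
#'   `B_map = 0`), `B_posterior` (data frame of counts and frequencies),
#'   `log_post`, and (when requested) `ci_lower`/`ci_upper` arrays of
#'   dimension `B_map x n_frames x 3`.
#' @export
map_estimate <- function(chain, ci = TRUE) {
  stopifnot(inherits(chain, "jt_chain"))
  if (length(chain$samples) == 0L) stop("empty chain", call. = FALSE)
  tab <- table(chain$B)
  B_map <- as.integer(names(tab)[which.max(tab)])
  idx <- which(chain$B == B_map)
  best <- idx[which.max(chain$log_post[idx])]
  state <- chain$samples[[best]]
  cfg <- chain$config
  tracks <- if (B_map > 0) state_tracks(state, cfg) else NULL
  out <- list(B_map = B_map, state = state, tracks = tracks,
              B_posterior = data.frame(B = as.integer(names(tab)),
                                       freq = as.numeric(tab) / sum(tab)),
              log_post = chain$log_post[best], sample_index = best)
  if (ci && B_map > 0 && length(chain$samples) >= 40L) {
    cis <- track_cis(chain, state, cfg)
    out$ci_lower <- cis$lower
    out$ci_upper <- cis$upper
  }
  structure(out, class = "track_estimate")
}

#' @export
print.track_estimate <- function(x, ...) {
  cat(sprintf("<track_estimate> B_MAP = %d (log posterior %.1f)\n",
              x$B_map, x$log_post))
  invisible(x)
}

# credible intervals for track coordinates by per-frame matching to MAP
track_cis <- function(chain, map_state, cfg) {
  N <- cfg$timing$n_frames
  K <- cfg$model$K
  act_map <- which(map_state$b == 1L)
  B <- length(act_map)
  grp <- rep(seq_len(N), each = K)
  frame_pos <- function(state, m)
    cbind(tapply(state$x[m, ], grp, mean), tapply(state$y[m, ], grp, mean),
          tapply(state$z[m, ], grp, mean))
  map_pos <- lapply(act_map, function(m) frame_pos(map_state, m))
  store <- lapply(seq_len(B), function(i)
    lapply(seq_len(N), function(n) list(x = numeric(0), y = numeric(0), z = numeric(0))))
  for (s in chain$samples) {
    act <- which(s$b == 1L)
    if (!length(act)) next
    sp <- lapply(act, function(m) frame_pos(s, m))
    for (n in seq_len(N)) {
      mp <- do.call(rbind, lapply(map_pos, function(pm) pm[n, , drop = FALSE]))
      pp <- do.call(rbind, lapply(sp, function(pm) pm[n, , drop = FALSE]))
      k1 <- nrow(mp); k2 <- nrow(pp)
      C <- outer(seq_len(k1), seq_len(k2), function(i, j)
        sqrt((mp[i, 1] - pp[j, 1])^2 + (mp[i, 2] - pp[j, 2])^2))
      transposed <- k1 > k2
      Cm <- if (transposed) t(C) else C
      sol <- as.integer(clue::solve_LSAP(Cm))
      pairs <- if (transposed) cbind(sol, seq_len(k2)) else cbind(seq_len(k1), sol)
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        st <- store[[i]][[n]]
        st$x <- c(st$x, pp[j, 1]); st$y <- c(st$y, pp[j, 2])
        st$z <- c(st$z, abs(pp[j, 3]))
        store[[i]][[n]] <- st
      }
    }
  }
  lower <- upper <- array(NA_real_, dim = c(B, N, 3),
                          dimnames = list(NULL, NULL, c("x", "y", "z")))
  for (i in seq_len(B)) for (n in seq_len(N)) {
    st <- store[[i]][[n]]
    for (j in 1:3) {
      v <- st[[j]]
      if (length(v) >= 2L) {
        qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
        lower[i, n, j] <- qs[1]; upper[i, n, j] <- qs[2]
      }
    }
  }
  list(lower = lower, upper = upper)
}

#' Percentile credible intervals of chain quantities
#'
#' 95% credible intervals as the 2.5th to 97.5th percentile range of the
#' retained posterior samples.
#'
#' @param chain A [run_chain()] result with at least 40 retained samples.
#' @param what One of `"D"`, `"h"`, `"F"`, `"B"`.
#' @param level Credible level (default 0.95).
#' @return For `"D"`: numeric `c(lower, upper)`.  For `"h"`/`"F"`: an
#'   `n_frames x 2` matrix.  For `"B"`: integer `c(lower, upper)`.
#' @export
credible_intervals <- function(chain, what = c("D", "h", "F", "B"),
                               level = 0.95) {
  stopifnot(inherits(chain, "jt_chain"))
  what <- match.arg(what)
  if (length(chain$samples) < 40L)
    stop("need at least 40 retained samples for credible intervals", call. = FALSE)
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (what == "D")
    return(stats::quantile(chain$D, pr, names = FALSE))
  if (what == "B")
    return(as.integer(stats::quantile(chain$B, pr, names = FALSE, type = 1)))
  N <- chain$config$timing$n_frames
  m <- t(vapply(chain$samples, function(s) rep_len(s[[if (what == "h") "h" else "F"]], N),
                numeric(N)))
  t(apply(m, 2, stats::quantile, probs = pr, names = FALSE))
}
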