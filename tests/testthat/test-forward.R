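test_that("PSF width is even in z, sigma0 in focus, nondecreasing in |z|", {
  op <- test_optics()
  expect_equal(psf_lateral_width(0, op), op$sigma0)
  expect_equal(psf_lateral_width(op$dz, op), op$sigma0 * sqrt(2))
  zs <- seq(-1500, 1500, by = 100)
  expect_equal(psf_lateral_width(zs, op), psf_lateral_width(-zs, op))
  w <- psf_lateral_width(abs(zs), op)
  expect_true(all(diff(w[order(abs(zs))]) >= -1e-12))
})

test_that("pixel-integrated emitter photons match 2D quadrature and conserve flux", {
  cam <- test_camera(n_px = 9)
  op <- test_optics()
  pos <- c(4.5 * 133, 4.5 * 133, 120)  # static, centred, slightly defocused
  h <- 5000; dt <- 0.1
  # quadrature oracle: numerically integrate the Gaussian over one pixel
  p <- pixel_at(4.5 * 133 + 140, 4.5 * 133 - 70, cam)
  reg <- pixel_region(p, cam)
  s <- psf_lateral_width(pos[3], op)
  g2 <- pracma::integral2(function(x, y)
    exp(-((x - pos[1])^2 + (y - pos[2])^2) / (2 * s^2)) / (2 * pi * s^2),
    reg[, "x_min"], reg[, "x_max"], reg[, "y_min"], reg[, "y_max"],
    reltol = 1e-10)$Q
  got <- emitter_pixel_photons(pos, h, p, cam, op, dt)
  expect_equal(got, h * dt * g2, tolerance = 1e-8)

  # symmetry of a centred emitter: 4 edge pixels equal, 4 corner pixels equal
  centre <- pixel_at(4.5 * 133, 4.5 * 133, cam)
  nbr <- function(dr, dc) centre + dr * cam$n_cols + dc
  edges <- emitter_pixel_photons(pos, h, c(nbr(-1, 0), nbr(1, 0), nbr(0, -1), nbr(0, 1)),
                                 cam, op, dt)
  corners <- emitter_pixel_photons(pos, h, c(nbr(-1, -1), nbr(-1, 1), nbr(1, -1), nbr(1, 1)),
                                   cam, op, dt)
  expect_equal(max(edges) - min(edges), 0, tolerance = 1e-12)
  expect_equal(max(corners) - min(corners), 0, tolerance = 1e-12)

  # photon conservation over a >= 10 sigma padded grid
  tot <- sum(emitter_pixel_photons(pos, h, seq_len(81), cam, op, dt))
  expect_equal(tot, h * dt, tolerance = 1e-6)
  expect_error(emitter_pixel_photons(pos, -5, 1, cam, op, dt), "brightness")
})

test_that("expected image is additive in active emitters with load semantics", {
  cfg <- test_config(n_px = 12, n_frames = 3, M = 3, K = 2)
  g <- subexposure_times(cfg$timing, cfg$model$K)
  S <- length(g$times)
  set.seed(5)
  mk_track <- function(cx, cy) cbind(cx + cumsum(rnorm(S, 0, 10)),
                                     cy + cumsum(rnorm(S, 0, 10)),
                                     rnorm(S, 0, 50))
  t1 <- mk_track(500, 500); t2 <- mk_track(1100, 900); t3 <- mk_track(300, 1200)
  st <- function(b) system_state(b,
    x = rbind(t1[, 1], t2[, 1], t3[, 1]), y = rbind(t1[, 2], t2[, 2], t3[, 2]),
    z = rbind(t1[, 3], t2[, 3], t3[, 3]), D = 1e4, h = c(5000, 5200, 4800),
    F = c(0.01, 0.012, 0.009))
  u0 <- expected_image(st(c(0L, 0L, 0L)), cfg)$u
  u1 <- expected_image(st(c(1L, 0L, 0L)), cfg)$u
  u2 <- expected_image(st(c(0L, 1L, 0L)), cfg)$u
  u12 <- expected_image(st(c(1L, 1L, 0L)), cfg)$u
  # background-only: F_n * area * dt in every pixel
  dt <- jointtrack:::exposure_durations(cfg$timing)
  expect_equal(u0, matrix(rep(c(0.01, 0.012, 0.009) * 133^2 * dt,
                              each = 144), nrow = 144))
  # exact additivity of emitter excesses (load linearity)
  expect_equal(u12, u1 + u2 - u0, tolerance = 1e-12)
  # b^m = 0 is identical to removing the emitter
  expect_identical(u0, expected_image(st(c(0L, 0L, 0L)), cfg)$u)
  # decomposition sums to the total exactly
  dec <- expected_image(st(c(1L, 1L, 1L)), cfg, decompose = TRUE)
  total <- dec$background + dec$per_emitter[[1]] + dec$per_emitter[[2]] +
    dec$per_emitter[[3]]
  expect_equal(dec$u, total, tolerance = 1e-12)
})

test_that("camera samples match the EMCCD mean and variance model", {
  cam <- test_camera(n_px = 1)
  tmg <- acquisition_timing(n_frames = 1, exposure = 0.1)
  n <- 1e5
  u <- matrix(100, 1, 1)
  big <- camera_sample(matrix(100, nrow = 1, ncol = n),
                       cam, acquisition_timing(n, 0.1), seed = 99)
  w <- as.numeric(big$values)
  mu_th <- cam$offset + cam$gain * 100
  var_th <- cam$read_variance + cam$excess_noise * cam$gain^2 * 100
  expect_lt(abs(mean(w) - mu_th), 4 * sqrt(var_th / n))
  expect_lt(abs(var(w) / var_th - 1), 0.05)
  # reproducibility
  s1 <- camera_sample(u, cam, tmg, seed = 7)
  s2 <- camera_sample(u, cam, tmg, seed = 7)
  expect_identical(s1$values, s2$values)
  expect_error(camera_sample(matrix(-1, 1, 1), cam, tmg), ">= 0")
})

test_that("log likelihood equals the closed-form normal density sum", {
  cam <- test_camera(n_px = 1)
  u <- matrix(c(3.7), 1, 1)
  w <- matrix(c(151.2), 1, 1)
  v <- cam$read_variance + cam$excess_noise * cam$gain^2 * 3.7
  m <- cam$offset + cam$gain * 3.7
  oracle <- -0.5 * log(2 * pi * v) - (151.2 - m)^2 / (2 * v)
  expect_equal(log_likelihood(w, u, cam), oracle, tolerance = 1e-12)
  # at the mode the density is maximal in w
  at_mode <- log_likelihood(matrix(m, 1, 1), u, cam)
  expect_equal(at_mode, -0.5 * log(2 * pi * v), tolerance = 1e-12)
  for (delta in c(1, 5, 20)) {
    expect_lt(log_likelihood(matrix(m + delta, 1, 1), u, cam), at_mode)
    expect_lt(log_likelihood(matrix(m + 2 * delta, 1, 1), u, cam),
              log_likelihood(matrix(m + delta, 1, 1), u, cam))
  }
  expect_error(log_likelihood(matrix(0, 2, 1), u, cam), "shape mismatch")
})

test_that("photon conservation holds for interior emitters of a full state", {
  cfg <- test_config(n_px = 20, n_frames = 4, M = 2, K = 4)
  g <- subexposure_times(cfg$timing, cfg$model$K)
  S <- length(g$times)
  set.seed(11)
  ctr <- 10 * 133
  st <- system_state(b = c(1L, 1L),
                     x = rbind(ctr + cumsum(rnorm(S, 0, 15)), ctr - 400 + cumsum(rnorm(S, 0, 15))),
                     y = rbind(ctr + cumsum(rnorm(S, 0, 15)), ctr + 300 + cumsum(rnorm(S, 0, 15))),
                     z = matrix(rnorm(2 * S, 0, 30), 2), D = 1e4,
                     h = rep(5000, 4), F = rep(0.01, 4))
  dec <- expected_image(st, cfg, decompose = TRUE)
  sig <- colSums(dec$u - dec$background)
  dt <- jointtrack:::exposure_durations(cfg$timing)
  expect_equal(sig, 2 * 5000 * dt, tolerance = 1e-6)
})

test_that("likelihood is invariant under relabeling active emitters", {
  cfg <- test_config(n_px = 10, n_frames = 2, M = 2, K = 2)
  S <- 4
  set.seed(3)
  xa <- 400 + cumsum(rnorm(S, 0, 10)); ya <- 500 + cumsum(rnorm(S, 0, 10))
  xb <- 900 + cumsum(rnorm(S, 0, 10)); yb <- 800 + cumsum(rnorm(S, 0, 10))
  za <- rnorm(S, 0, 20); zb <- rnorm(S, 0, 20)
  st1 <- system_state(c(1L, 1L), rbind(xa, xb), rbind(ya, yb), rbind(za, zb),
                      1e4, rep(5000, 2), rep(0.01, 2))
  st2 <- system_state(c(1L, 1L), rbind(xb, xa), rbind(yb, ya), rbind(zb, za),
                      1e4, rep(5000, 2), rep(0.01, 2))
  w <- camera_sample(expected_image(st1, cfg), cfg$camera, cfg$timing, seed = 1)
  expect_equal(log_likelihood(w, expected_image(st1, cfg)),
               log_likelihood(w, expected_image(st2, cfg)), tolerance = 1e-10)
})
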