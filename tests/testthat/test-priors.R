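test_that("loads prior is the truncated Beta-Bernoulli mass function", {
  b0 <- rep(0L, 10)
  expect_equal(loads_log_prior(b0, 10, gamma = 1), 10 * log(0.9), tolerance = 1e-12)
  # exchangeability
  b <- c(1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L)
  set.seed(1)
  for (i in 1:5) {
    expect_equal(loads_log_prior(sample(b), 10, gamma = 2),
                 loads_log_prior(b, 10, gamma = 2))
  }
  # normalization: summing over all 2^M configurations gives 1 (M = 10)
  grid <- as.matrix(expand.grid(rep(list(0:1), 10)))
  probs <- exp(apply(grid, 1, function(bb) loads_log_prior(bb, 10, gamma = 2.5)))
  expect_equal(sum(probs), 1, tolerance = 1e-10)
  # expected active count is gamma exactly under the truncated construction
  expect_equal(sum(rowSums(grid) * probs), 2.5, tolerance = 1e-10)
  expect_error(loads_log_prior(b0, 10, gamma = 10), "gamma")
})

test_that("prior predictive of the active count approaches Poisson(gamma)", {
  # Binomial(M, gamma / M) vs Poisson(gamma) at M = 1000: total variation
  gamma <- 5; M <- 1000
  k <- 0:40
  tv <- 0.5 * sum(abs(dbinom(k, M, gamma / M) - dpois(k, gamma)))
  expect_lt(tv, 0.01)
  # and is far from Poisson at tiny M
  tv_small <- 0.5 * sum(abs(dbinom(0:8, 8, gamma / 8) - dpois(0:8, gamma)))
  expect_gt(tv_small, tv)
})

test_that("motion prior factorizes over Markov steps and peaks at zero displacement", {
  cfg <- test_config(n_px = 8, n_frames = 2, K = 2)
  g <- subexposure_times(cfg$timing, 2)
  S <- length(g$times)
  start <- c(500, 500, 0)
  still <- matrix(rep(start, each = S), S)
  set.seed(2)
  moved <- still + cbind(c(0, cumsum(rnorm(S - 1, 0, 30))),
                         c(0, cumsum(rnorm(S - 1, 0, 30))), 0)
  expect_gt(motion_log_prob(still, 1e4, cfg), motion_log_prob(moved, 1e4, cfg))
  # Markov additivity: total = init + sum of one-step transition terms
  sd_step <- sqrt(2 * 1e4 * g$dt)
  manual <- jointtrack:::initial_log_density(moved[1, 1], moved[1, 2], moved[1, 3], cfg)
  for (j in 1:3)
    manual <- manual + sum(dnorm(diff(moved[, j]), 0, sd_step, log = TRUE))
  expect_equal(motion_log_prob(moved, 1e4, cfg), manual, tolerance = 1e-10)
  expect_error(motion_log_prob(moved, -1, cfg), "D must be")
  # track starting outside the expanded FOV has zero prior density
  out <- still; out[1, 1] <- -10 * 133
  expect_identical(motion_log_prob(out, 1e4, cfg), -Inf)
})

test_that("average motion negative log-probability matches the step entropy", {
  cfg <- test_config(n_px = 16, n_frames = 10, K = 2)
  g <- subexposure_times(cfg$timing, 2)
  D <- 1e4
  scen <- scenario(cfg, motion = "brownian", D = D, B_true = 1, seed = 1)
  set.seed(9)
  nll <- replicate(300, {
    tr <- jointtrack:::simulate_one_track(c(1000, 1000, 0), g, scen)
    lp <- motion_log_prob(tr, D, cfg) -
      jointtrack:::initial_log_density(tr[1, 1], tr[1, 2], tr[1, 3], cfg)
    -lp / (nrow(tr) - 1)
  })
  entropy <- sum(0.5 * log(2 * pi * exp(1) * 2 * D * g$dt)) / length(g$dt) * 3
  expect_equal(mean(nll), entropy, tolerance = 3 * sd(nll) / sqrt(300) / entropy + 0.01)
})

test_that("parameter priors: exponential special case, mode, independence", {
  mc <- model_config(h_shape = 1, h_scale = 1000, f_shape = 2, f_scale = 5e-3,
                     d_shape = 2, d_scale = 1e4)
  # Gamma(shape 1) is exponential: log prior linear in h
  l1 <- params_log_prior(1e4, 500, 0.01, mc)
  l2 <- params_log_prior(1e4, 1500, 0.01, mc)
  l3 <- params_log_prior(1e4, 2500, 0.01, mc)
  expect_equal(l2 - l1, l3 - l2, tolerance = 1e-10)
  # Inverse-Gamma mode of D prior at scale / (shape + 1)
  mode <- 1e4 / 3
  eps <- 1
  expect_gt(params_log_prior(mode, 500, 0.01, mc),
            params_log_prior(mode + 50, 500, 0.01, mc))
  expect_gt(params_log_prior(mode, 500, 0.01, mc),
            params_log_prior(mode - 50, 500, 0.01, mc))
  # density value at a point matches the closed form
  d_oracle <- function(x, a, s) a * log(s) - lgamma(a) - (a + 1) * log(x) - s / x
  expect_equal(params_log_prior(5e3, 500, 0.01, mc),
               d_oracle(5e3, 2, 1e4) +
                 dgamma(500, 1, scale = 1000, log = TRUE) +
                 dgamma(0.01, 2, scale = 5e-3, log = TRUE), tolerance = 1e-12)
  # doubling one frame's h changes only that frame's term
  la <- params_log_prior(1e4, c(500, 700), c(0.01, 0.01), mc)
  lb <- params_log_prior(1e4, c(500, 1400), c(0.01, 0.01), mc)
  lc <- params_log_prior(1e4, c(250, 700), c(0.01, 0.01), mc)
  expect_equal(lb - la,
               dgamma(1400, 1, scale = 1000, log = TRUE) -
                 dgamma(700, 1, scale = 1000, log = TRUE), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(lb - la, lc - la)))
})

test_that("log posterior is the exact sum of its components", {
  cfg <- test_config(n_px = 10, n_frames = 3, M = 3, K = 2, gamma = 1)
  g <- subexposure_times(cfg$timing, 2)
  S <- length(g$times)
  set.seed(7)
  mk <- function(cx, cy) cbind(cx + cumsum(rnorm(S, 0, 15)),
                               cy + cumsum(rnorm(S, 0, 15)), rnorm(S, 0, 30))
  trks <- list(mk(400, 500), mk(900, 800), mk(600, 300))
  st <- system_state(c(1L, 0L, 1L),
                     x = do.call(rbind, lapply(trks, `[`, , 1)),
                     y = do.call(rbind, lapply(trks, `[`, , 2)),
                     z = do.call(rbind, lapply(trks, `[`, , 3)),
                     D = 8e3, h = rep(5000, 3), F = rep(0.01, 3))
  w <- camera_sample(expected_image(st, cfg), cfg$camera, cfg$timing, seed = 2)
  manual <- log_likelihood(w, expected_image(st, cfg)) +
    loads_log_prior(st$b, 3, cfg$model$gamma) +
    motion_log_prob(trks[[1]], 8e3, cfg) +
    motion_log_prob(trks[[2]], cfg$model$d_ref, cfg) +
    motion_log_prob(trks[[3]], 8e3, cfg) +
    params_log_prior(8e3, st$h, st$F, cfg$model)
  expect_equal(state_log_posterior(st, w, cfg), manual, tolerance = 1e-10)
  # prior-only variant drops exactly the likelihood term
  expect_equal(state_log_posterior(st, w, cfg) -
                 state_log_posterior(st, NULL, cfg, include_likelihood = FALSE),
               log_likelihood(w, expected_image(st, cfg)), tolerance = 1e-10)
})

test_that("posterior is invariant under jointly permuting active emitters", {
  cfg <- test_config(n_px = 10, n_frames = 2, M = 2, K = 2, gamma = 1)
  S <- 4
  set.seed(8)
  t1 <- cbind(400 + cumsum(rnorm(S, 0, 10)), 500 + cumsum(rnorm(S, 0, 10)),
              rnorm(S, 0, 20))
  t2 <- cbind(900 + cumsum(rnorm(S, 0, 10)), 700 + cumsum(rnorm(S, 0, 10)),
              rnorm(S, 0, 20))
  st12 <- system_state(c(1L, 1L), rbind(t1[, 1], t2[, 1]), rbind(t1[, 2], t2[, 2]),
                       rbind(t1[, 3], t2[, 3]), 1e4, rep(5000, 2), rep(0.01, 2))
  st21 <- system_state(c(1L, 1L), rbind(t2[, 1], t1[, 1]), rbind(t2[, 2], t1[, 2]),
                       rbind(t2[, 3], t1[, 3]), 1e4, rep(5000, 2), rep(0.01, 2))
  w <- camera_sample(expected_image(st12, cfg), cfg$camera, cfg$timing, seed = 3)
  expect_equal(state_log_posterior(st12, w, cfg), state_log_posterior(st21, w, cfg),
               tolerance = 1e-10)
})
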