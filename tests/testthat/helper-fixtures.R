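# Shared builders for small test scenes and independent oracles.

test_camera <- function(n_px = 16, pixel_size = 133) {
  camera_model(offset = 100, read_variance = 25, gain = 10, excess_noise = 2,
               pixel_size = pixel_size, n_rows = n_px, n_cols = n_px)
}

test_optics <- function() optics_model(na = 1.49, wavelength = 684, dz = 500)

test_timing <- function(n_frames = 22, exposure = 0.1) {
  acquisition_timing(n_frames = n_frames, exposure = exposure)
}

test_config <- function(n_px = 16, n_frames = 22, M = 10, K = 4,
                        gamma = min(3, M / 2), run = run_config()) {
  validate_config(test_camera(n_px), test_optics(), test_timing(n_frames),
                  model_config(M = M, K = K, gamma = gamma), run)
}

# a simple track set from a list of n_frames x d position matrices
ts_from_mats <- function(mats, n_frames = nrow(mats[[1]])) {
  rows <- do.call(rbind, lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    if (ncol(m) == 2) m <- cbind(m, NA_real_)
    data.frame(track = paste0("t", i), frame = seq_len(nrow(m)),
               x = m[, 1], y = m[, 2], z = m[, 3],
               present = is.finite(m[, 1]))
  }))
  rows <- rows[rows$present | TRUE, ]
  track_set(rows, n_frames = n_frames)
}

# random complete 2D tracks for oracle checks
random_track_set <- function(n_tracks, n_frames, scale = 1000) {
  mats <- lapply(seq_len(n_tracks), function(i)
    cbind(stats::runif(n_frames, 0, scale), stats::runif(n_frames, 0, scale)))
  ts_from_mats(mats)
}

# Brute-force pairing oracle: enumerate all injections between the two sets
# (tracks may also stay unmatched at cost epsilon * N) and minimize.
brute_force_pairing <- function(psi_set, phi_set, epsilon) {
  N <- n_frames(psi_set)
  A <- lapply(track_ids(psi_set), function(id) track_matrix(psi_set, id))
  B <- lapply(track_ids(phi_set), function(id) track_matrix(phi_set, id))
  n1 <- length(A); n2 <- length(B)
  C <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    C[i, j] <- gated_track_distance(A[[i]], B[[j]], epsilon)
  best <- Inf
  # assignments: each psi-track gets a phi-track index or 0 (unmatched)
  assign_next <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > n1) {
      total <- cost + epsilon * N * sum(!used)  # unmatched phi tracks
      if (total < best) best <<- total
      return()
    }
    assign_next(i + 1L, used, cost + epsilon * N)  # psi_i unmatched
    for (j in seq_len(n2)) if (!used[j]) {
      used[j] <- TRUE
      assign_next(i + 1L, used, cost + C[i, j])
      used[j] <- FALSE
    }
  }
  if (is.infinite(epsilon)) {
    # match all of the smaller set; unmatched tracks cost nothing
    k <- min(n1, n2)
    best <- Inf
    perms <- all_perms(max(n1, n2))
    for (p in perms) {
      if (n1 <= n2) total <- sum(C[cbind(seq_len(n1), p[seq_len(n1)])])
      else total <- sum(C[cbind(p[seq_len(n2)], seq_len(n2))])
      if (total < best) best <- total
    }
    return(best)
  }
  assign_next(1L, rep(FALSE, n2), 0)
  best
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}

# per-frame identity-free oracle for localization resolution
brute_force_resolution <- function(psi_set, phi_set) {
  N <- n_frames(psi_set)
  A <- lapply(track_ids(psi_set), function(id) track_matrix(psi_set, id))
  B <- lapply(track_ids(phi_set), function(id) track_matrix(phi_set, id))
  total <- 0; npairs <- 0L
  for (n in seq_len(N)) {
    pa <- do.call(rbind, lapply(A, function(m) m[n, , drop = FALSE]))
    pb <- do.call(rbind, lapply(B, function(m) m[n, , drop = FALSE]))
    pa <- pa[is.finite(pa[, 1]), , drop = FALSE]
    pb <- pb[is.finite(pb[, 1]), , drop = FALSE]
    k <- nrow(pa)
    if (k == 0L) next
    use_z <- all(is.finite(pa[, 3])) && all(is.finite(pb[, 3]))
    dfun <- function(i, j) {
      dd <- (pa[i, 1] - pb[j, 1])^2 + (pa[i, 2] - pb[j, 2])^2
      if (use_z) dd <- dd + (abs(pa[i, 3]) - abs(pb[j, 3]))^2
      sqrt(dd)
    }
    best <- Inf
    for (p in all_perms(k)) {
      tot <- sum(vapply(seq_len(k), function(i) dfun(i, p[i]), numeric(1)))
      if (tot < best) best <- tot
    }
    total <- total + best
    npairs <- npairs + k
  }
  total / npairs
}

# lateral-only view of a track set
lateral_only <- function(ts) {
  ts$z <- NA_real_
  ts
}
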