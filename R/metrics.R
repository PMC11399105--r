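# Track-comparison metrics: gated distance, optimal pairing, tracking error,
# dual-view tracking error and localization resolution.

# Decide which coordinates two position matrices share: lateral always;
# axial only when both carry finite z everywhere they are present.  Axial
# positions are compared as |z| vs |z| (the sign is not identifiable).
shared_coords <- function(a, b) {
  has_z <- function(m) {
    pres <- is.finite(m[, 1])
    any(pres) && all(is.finite(m[pres, 3]))
  }
  if (has_z(a) && has_z(b)) 3L else 2L
}

frame_distances <- function(a, b, d) {
  dx <- a[, 1] - b[, 1]
  dy <- a[, 2] - b[, 2]
  if (d == 3L) {
    dz <- abs(a[, 3]) - abs(b[, 3])
    sqrt(dx^2 + dy^2 + dz^2)
  } else {
    sqrt(dx^2 + dy^2)
  }
}

#' Gated Euclidean distance between two tracks
#'
#' Sum over frames of `min(||psi_n - phi_n||, epsilon)`.  When either track
#' has no localization in a frame, that frame contributes the gate value
#' `epsilon`.  With an infinite gate, absent frames are not allowed (an
#' infinite gate is reserved for comparisons between complete tracks).
#' Tracks may be lateral-only or 3D; when one side lacks axial positions the
#' comparison uses the shared lateral coordinates, and axial positions are
#' compared as absolute values.
#'
#' @param psi,phi `n_frames x 2` or `n_frames x 3` position matrices in nm
#'   (`NA` rows = no localization that frame).
#' @param epsilon Gate value, nm (> 0); may be `Inf`.
#' @return Total gated distance, nm.
#' @export
gated_track_distance <- function(psi, phi, epsilon) {
  psi <- as_positions(psi); phi <- as_positions(phi)
  if (nrow(psi) != nrow(phi))
    stop(sprintf("tracks cover different frame ranges (%d vs %d)",
                 nrow(psi), nrow(phi)), call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("gate epsilon must be > 0", call. = FALSE)
  both <- is.finite(psi[, 1]) & is.finite(phi[, 1])
  if (!all(both) && is.infinite(epsilon))
    stop("absent frames are not allowed with an infinite gate", call. = FALSE)
  d <- shared_coords(psi, phi)
  dist <- frame_distances(psi[both, , drop = FALSE], phi[both, , drop = FALSE], d)
  n_absent <- sum(!both)
  sum(pmin(dist, epsilon)) + if (n_absent) epsilon * n_absent else 0
}

as_positions <- function(m) {
  m <- as.matrix(m)
  if (!ncol(m) %in% 2:3) stop("positions must have 2 or 3 columns", call. = FALSE)
  if (ncol(m) == 2L) m <- cbind(m, NA_real_)
  m
}

track_mats <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  lapply(track_ids(ts), function(id) track_matrix(ts, id))
}

#' Optimal pairing between two track sets
#'
#' Minimum total gated distance over all one-to-one pairings between two
#' track sets, solved as a linear assignment problem on the matrix of
#' pairwise [gated_track_distance()] values augmented with dummy partners:
#' a track left unmatched costs `epsilon * n_frames` (it fails localization
#' in every frame).  With `epsilon = Inf` all tracks of the smaller set are
#' matched (complete tracks required) and unmatched tracks of the larger set
#' contribute nothing.
#'
#' @param psi_set,phi_set [track_set()] objects on the same frame axis.
#' @param epsilon Gate value, nm; may be `Inf`.
#' @return Object of class `pairing_result`: list with `pairs` (data frame of
#'   matched track ids and their gated distances), `unmatched_psi`,
#'   `unmatched_phi`, `total` (pairing distance, nm), `epsilon`, `n_frames`.
#' @export
pair_track_sets <- function(psi_set, phi_set, epsilon) {
  if (n_frames(psi_set) != n_frames(phi_set))
    stop("track sets cover different frame axes", call. = FALSE)
  N <- n_frames(psi_set)
  A <- track_mats(psi_set); B <- track_mats(phi_set)
  ida <- track_ids(psi_set); idb <- track_ids(phi_set)
  n1 <- length(A); n2 <- length(B)
  C <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    C[i, j] <- gated_track_distance(A[[i]], B[[j]], epsilon)

  if (is.infinite(epsilon)) {
    # rectangular assignment: match all of the smaller set
    transposed <- n1 > n2
    Cm <- if (transposed) t(C) else C
    sol <- as.integer(clue::solve_LSAP(Cm))
    if (transposed) {
      pairs <- data.frame(psi = ida[sol], phi = idb[seq_len(n2)])
      cost <- Cm[cbind(seq_len(n2), sol)]
    } else {
      pairs <- data.frame(psi = ida[seq_len(n1)], phi = idb[sol])
      cost <- Cm[cbind(seq_len(n1), sol)]
    }
    pairs$distance <- cost
    total <- sum(cost)
  } else {
    # square augmentation with per-track dummy partners costing epsilon * N
    big <- (n1 + n2 + 1) * epsilon * N + 1
    S <- matrix(big, n1 + n2, n1 + n2)
    S[seq_len(n1), seq_len(n2)] <- C
    for (i in seq_len(n1)) S[i, n2 + i] <- epsilon * N
    for (j in seq_len(n2)) S[n1 + j, j] <- epsilon * N
    S[(n1 + 1):(n1 + n2), (n2 + 1):(n2 + n1)] <- 0
    sol <- as.integer(clue::solve_LSAP(S))
    real <- which(seq_len(n1 + n2) <= n1 & sol <= n2)
    pairs <- data.frame(psi = ida[real], phi = idb[sol[real]])
    pairs$distance <- C[cbind(real, sol[real])]
    total <- sum(pairs$distance) +
      epsilon * N * (n1 - nrow(pairs)) + epsilon * N * (n2 - nrow(pairs))
  }
  structure(list(pairs = pairs,
                 unmatched_psi = setdiff(ida, pairs$psi),
                 unmatched_phi = setdiff(idb, pairs$phi),
                 total = total, epsilon = epsilon, n_frames = N),
            class = "pairing_result")
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf("<pairing_result> %d pairs, %d + %d unmatched; total gated distance %.2f nm (gate %s)\n",
              nrow(x$pairs), length(x$unmatched_psi), length(x$unmatched_phi),
              x$total, format(x$epsilon)))
  invisible(x)
}

#' Tracking error against a reference track set
#'
#' Pairing distance between the estimated and the reference set (ground
#' truth when available), normalized per reference track and frame:
#' `total / (n_frames * n_ref_tracks)`, in nm.
#'
#' @param psi_set Estimated [track_set()].
#' @param ref_set Reference [track_set()] (>= 1 track).
#' @param epsilon Gate value, nm.
#' @return Tracking error, nm per emitter per frame.
#' @export
tracking_error <- function(psi_set, ref_set, epsilon) {
  if (n_tracks(ref_set) < 1L) stop("reference set is empty", call. = FALSE)
  pr <- pair_track_sets(psi_set, ref_set, epsilon)
  pr$total / (n_frames(ref_set) * n_tracks(ref_set))
}

#' Dual-view tracking error
#'
#' Tracking error between two estimates of the same scene from two cameras,
#' with no ground truth: the pairing distance with an infinite gate (both
#' views produce complete tracks) divided by `2 * n_frames * M`, the factor
#' of two because the pairing distance sums errors of both views so the
#' error per view is half.  When the views disagree on the number of tracks,
#' `M` is their mean.
#'
#' @param set1,set2 Complete [track_set()] objects (no absent frames).
#' @return Tracking error, nm per emitter per frame per view.
#' @export
dual_view_tracking_error <- function(set1, set2) {
  for (s in list(set1, set2))
    if (!all(s$present)) stop("dual-view comparison requires complete tracks", call. = FALSE)
  pr <- pair_track_sets(set1, set2, Inf)
  M <- mean(c(n_tracks(set1), n_tracks(set2)))
  pr$total / (2 * n_frames(set1) * M)
}

#' Localization resolution
#'
#' Identity-free localization accuracy: in every frame the positions of the
#' two sets are optimally paired without regard to track identity and
#' without a gate; the metric is the mean paired distance over all frames
#' and pairs.  Insensitive to mislinks by construction; undefined (error)
#' when the two sets do not hold the same number of positions in every
#' frame.  Equals the tracking error when there are no mislinks, false
#' positives or false negatives.
#'
#' @param psi_set,phi_set [track_set()] objects on the same frame axis.
#' @return Mean paired distance, nm.
#' @export
localization_resolution <- function(psi_set, phi_set) {
  if (n_frames(psi_set) != n_frames(phi_set))
    stop("track sets cover different frame axes", call. = FALSE)
  N <- n_frames(psi_set)
  A <- track_mats(psi_set); B <- track_mats(phi_set)
  total <- 0; npairs <- 0L
  for (n in seq_len(N)) {
    pa <- do.call(rbind, lapply(A, function(m) m[n, , drop = FALSE]))
    pb <- do.call(rbind, lapply(B, function(m) m[n, , drop = FALSE]))
    pa <- pa[is.finite(pa[, 1]), , drop = FALSE]
    pb <- pb[is.finite(pb[, 1]), , drop = FALSE]
    if (nrow(pa) != nrow(pb))
      stop(sprintf("frame %d: %d vs %d positions; localization resolution undefined",
                   n, nrow(pa), nrow(pb)), call. = FALSE)
    k <- nrow(pa)
    if (k == 0L) next
    d <- shared_coords(pa, pb)
    Cn <- matrix(0, k, k)
    for (i in seq_len(k))
      Cn[i, ] <- frame_distances(pa[rep(i, k), , drop = FALSE], pb, d)
    sol <- as.integer(clue::solve_LSAP(Cn))
    total <- total + sum(Cn[cbind(seq_len(k), sol)])
    npairs <- npairs + k
  }
  if (npairs == 0L) stop("no positions to compare", call. = FALSE)
  total / npairs
}

#' Convert a gate value in pixels to nm
#'
#' @param pixels Gate value in pixels.
#' @param camera A [camera_model()] (or pixel size in nm).
#' @return Gate value in nm.
#' @examples
#' gate_nm(5, 133)  # 665 nm, the default truth-comparison gate
#' @export
gate_nm <- function(pixels, camera) {
  ps <- if (inherits(camera, "camera_model")) camera$pixel_size else camera
  pixels * ps
}
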