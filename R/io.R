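# File formats: multi-page TIFF stacks, CSV tracks (canonical), TrackMate
# flavoured XML (interop), YAML configuration, chain archive.  Units are nm
# and seconds internally; conversions happen only at these boundaries.

#' Read a timelapse image stack from a multi-page TIFF
#'
#' One grayscale page per exposure, values passed through unscaled (analog
#' to digital units).  Page dimensions must match the camera geometry and
#' the page count the timing's frame count.
#'
#' @param path TIFF file.
#' @param camera A [camera_model()].
#' @param timing An [acquisition_timing()].
#' @return An [image_stack()].
#' @export
read_stack <- function(path, camera, timing) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != timing$n_frames)
    stop(sprintf("TIFF has %d pages but timing declares %d frames",
                 length(pages), timing$n_frames), call. = FALSE)
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L)
        stop(sprintf("page %d is not grayscale (%d channels)", i, dim(p)[3]),
             call. = FALSE)
      p <- p[, , 1]
    }
    if (nrow(p) != camera$n_rows || ncol(p) != camera$n_cols)
      stop(sprintf("page %d is %d x %d but camera declares %d x %d",
                   i, nrow(p), ncol(p), camera$n_rows, camera$n_cols),
           call. = FALSE)
    pages[[i]] <- p
  }
  values <- array(unlist(pages), dim = c(camera$n_rows, camera$n_cols,
                                         length(pages)))
  image_stack(values, timing, camera)
}

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' Counts are rounded and clamped to the 16-bit range.
#'
#' @param stack An [image_stack()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  N <- stack$timing$n_frames
  pages <- lapply(seq_len(N), function(n) {
    v <- round(stack$values[, , n])
    pmin(pmax(v, 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

# ---- track CSV --------------------------------------------------------------

#' Write tracks to CSV (canonical format)
#'
#' Columns: `track_id`, `frame`, `t_seconds`, `x_nm`, `y_nm`, `abs_z_nm`
#' (axial positions are reported as absolute values, their sign being
#' unidentifiable), plus `{x,y,z}_ci_{lo,hi}` when a [map_estimate()] with
#' credible intervals is written.  Absent frames are omitted.
#'
#' @param tracks A [track_set()] or [map_estimate()] `track_estimate`.
#' @param path Output CSV file.
#' @param timing Optional [acquisition_timing()] to fill `t_seconds` with
#'   exposure midpoints.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, timing = NULL) {
  ci <- NULL
  if (inherits(tracks, "track_estimate")) {
    est <- tracks
    tracks <- est$tracks
    if (is.null(tracks)) stop("estimate has no tracks (B_MAP = 0)", call. = FALSE)
    if (!is.null(est$ci_lower)) ci <- est
  }
  stopifnot(inherits(tracks, "track_set"))
  df <- tracks[tracks$present, ]
  tmid <- if (!is.null(timing)) (timing$t_min + timing$t_max) / 2 else rep(NA_real_, n_frames(tracks))
  ids <- track_ids(tracks)
  out <- data.frame(track_id = df$track, frame = df$frame,
                    t_seconds = tmid[df$frame],
                    x_nm = df$x, y_nm = df$y, abs_z_nm = abs(df$z))
  if (!is.null(ci)) {
    i <- match(df$track, ids)
    out$x_ci_lo <- ci$ci_lower[cbind(i, df$frame, 1)]
    out$x_ci_hi <- ci$ci_upper[cbind(i, df$frame, 1)]
    out$y_ci_lo <- ci$ci_lower[cbind(i, df$frame, 2)]
    out$y_ci_hi <- ci$ci_upper[cbind(i, df$frame, 2)]
    out$z_ci_lo <- ci$ci_lower[cbind(i, df$frame, 3)]
    out$z_ci_hi <- ci$ci_upper[cbind(i, df$frame, 3)]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read tracks from the canonical CSV format
#'
#' @param path CSV file written by [write_tracks()] (or with compatible
#'   columns `track_id`, `frame`, `x_nm`, `y_nm`, optionally `abs_z_nm`).
#' @param n_frames Frame-axis length (default: largest frame present).
#' @return A [track_set()].
#' @export
read_tracks <- function(path, n_frames = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x_nm", "y_nm")
  if (!all(need %in% names(df)))
    stop("CSV lacks the canonical track columns", call. = FALSE)
  out <- data.frame(track = as.character(df$track_id), frame = df$frame,
                    x = df$x_nm, y = df$y_nm,
                    z = if ("abs_z_nm" %in% names(df)) df$abs_z_nm else NA_real_,
                    present = TRUE)
  if (is.null(n_frames)) n_frames <- max(out$frame)
  track_set(out, n_frames = n_frames)
}

# ---- TrackMate-flavoured XML ------------------------------------------------

#' Write tracks as TrackMate-compatible XML
#'
#' Emits the minimal spot/edge element set understood by TrackMate importers
#' (spots grouped by frame, one `Track` of edges per track, a
#' `FilteredTracks` list).  Positions are converted from nm to the
#' consumer's pixel units; frames are 0-based in the file.
#'
#' @param tracks A [track_set()].
#' @param path Output XML file.
#' @param camera A [camera_model()] (for the nm to pixel conversion).
#' @return `path`, invisibly.
#' @export
write_trackmate_xml <- function(tracks, path, camera) {
  stopifnot(inherits(tracks, "track_set"), inherits(camera, "camera_model"))
  ps <- camera$pixel_size
  doc <- xml2::xml_new_root("TrackMate", version = "7.9.2")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = "pixel",
                               timeunits = "frame")
  df <- tracks[tracks$present, ]
  df$spot_id <- seq_len(nrow(df)) + 999L
  all_spots <- xml2::xml_add_child(model, "AllSpots",
                                   nspots = as.character(nrow(df)))
  for (fr in sort(unique(df$frame))) {
    sif <- xml2::xml_add_child(all_spots, "SpotsInFrame",
                               frame = as.character(fr - 1L))
    rows <- df[df$frame == fr, ]
    for (i in seq_len(nrow(rows))) {
      z <- rows$z[i]
      xml2::xml_add_child(sif, "Spot",
        ID = as.character(rows$spot_id[i]),
        name = paste0("ID", rows$spot_id[i]),
        QUALITY = "1.0", VISIBILITY = "1", RADIUS = "2.5",
        POSITION_X = format(rows$x[i] / ps, digits = 12),
        POSITION_Y = format(rows$y[i] / ps, digits = 12),
        POSITION_Z = format(if (is.finite(z)) abs(z) / ps else 0, digits = 12),
        POSITION_T = as.character(rows$frame[i] - 1L),
        FRAME = as.character(rows$frame[i] - 1L))
    }
  }
  all_tracks <- xml2::xml_add_child(model, "AllTracks")
  filtered <- xml2::xml_add_child(model, "FilteredTracks")
  ids <- track_ids(tracks)
  for (k in seq_along(ids)) {
    rows <- df[df$track == ids[k], ]
    rows <- rows[order(rows$frame), ]
    trk <- xml2::xml_add_child(all_tracks, "Track",
                               name = paste0("Track_", k - 1L),
                               TRACK_ID = as.character(k - 1L),
                               NUMBER_SPOTS = as.character(nrow(rows)))
    if (nrow(rows) > 1L) {
      for (i in seq_len(nrow(rows) - 1L)) {
        xml2::xml_add_child(trk, "Edge",
                            SPOT_SOURCE_ID = as.character(rows$spot_id[i]),
                            SPOT_TARGET_ID = as.character(rows$spot_id[i + 1L]),
                            LINK_COST = "-1.0")
      }
    }
    xml2::xml_add_child(filtered, "TrackID", TRACK_ID = as.character(k - 1L))
  }
  xml2::xml_add_child(doc, "Settings")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read tracks from TrackMate-style XML
#'
#' Parses the spot/edge structure written by [write_trackmate_xml()] or by
#' TrackMate itself; positions are converted from pixel units to nm.
#'
#' @param path XML file.
#' @param camera A [camera_model()] (pixel size for the unit conversion).
#' @param n_frames Frame-axis length (default: largest frame present).
#' @return A [track_set()].
#' @export
read_trackmate_xml <- function(path, camera, n_frames = NULL) {
  ps <- camera$pixel_size
  doc <- xml2::read_xml(path)
  spots <- xml2::xml_find_all(doc, ".//Spot")
  if (!length(spots)) stop("no spots in XML", call. = FALSE)
  sid <- xml2::xml_attr(spots, "ID")
  sdf <- data.frame(
    id = sid,
    frame = as.integer(xml2::xml_attr(spots, "FRAME")) + 1L,
    x = as.numeric(xml2::xml_attr(spots, "POSITION_X")) * ps,
    y = as.numeric(xml2::xml_attr(spots, "POSITION_Y")) * ps,
    z = as.numeric(xml2::xml_attr(spots, "POSITION_Z")) * ps,
    stringsAsFactors = FALSE)
  tracks <- xml2::xml_find_all(doc, ".//AllTracks/Track")
  rows <- NULL
  for (trk in tracks) {
    tid <- xml2::xml_attr(trk, "TRACK_ID")
    edges <- xml2::xml_find_all(trk, "./Edge")
    ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                    xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    if (!length(ids)) next
    sub <- sdf[sdf$id %in% ids, ]
    rows <- rbind(rows, data.frame(track = paste0("t", tid), frame = sub$frame,
                                   x = sub$x, y = sub$y, z = sub$z,
                                   present = TRUE))
  }
  if (is.null(rows)) stop("no tracks with edges in XML", call. = FALSE)
  if (is.null(n_frames)) n_frames <- max(rows$frame)
  track_set(rows, n_frames = n_frames)
}

# ---- configuration files ----------------------------------------------------

#' Read a YAML configuration file
#'
#' Documented key set (nested sections): `camera.{offset, read_variance,
#' gain, excess_noise, pixel_size, rows, cols}`, `optics.{na, wavelength,
#' sigma0, dz}`, `timing.{n_frames, exposure, period}`, `model.{M, K, gamma,
#' d_shape, d_scale, h_shape, h_scale, f_shape, f_scale, z_max,
#' fov_margin_px, d_ref}`, `run.{iterations, burn_in, thin, seed,
#' estimate_brightness, background, fixed_h, n_birth}`.  Missing model/run
#' keys fall back to defaults.
#'
#' @param path YAML file.
#' @return A validated `jt_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (sec in c("camera", "optics", "timing"))
    if (is.null(y[[sec]])) stop_field(sec, "section missing from config file")
  cam <- y$camera
  camera <- camera_model(cam$offset, cam$read_variance, cam$gain,
                         cam$excess_noise, cam$pixel_size, cam$rows, cam$cols)
  op <- y$optics
  optics <- do.call(optics_model, c(list(na = op$na, wavelength = op$wavelength),
                                    op[intersect(names(op), c("sigma0", "dz"))]))
  tm <- y$timing
  timing <- acquisition_timing(tm$n_frames, tm$exposure,
                               period = if (is.null(tm$period)) tm$exposure else tm$period)
  model <- do.call(model_config, y$model %||% list())
  run <- do.call(run_config, y$run %||% list())
  validate_config(camera, optics, timing, model, run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a configuration to YAML
#'
#' @param config A `jt_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "jt_config"))
  cam <- config$camera; op <- config$optics; tm <- config$timing
  y <- list(
    camera = list(offset = cam$offset, read_variance = cam$read_variance,
                  gain = cam$gain, excess_noise = cam$excess_noise,
                  pixel_size = cam$pixel_size, rows = cam$n_rows,
                  cols = cam$n_cols),
    optics = list(na = op$na, wavelength = op$wavelength,
                  sigma0 = op$sigma0, dz = op$dz),
    timing = list(n_frames = tm$n_frames,
                  exposure = tm$t_max[1] - tm$t_min[1],
                  period = if (tm$n_frames > 1) tm$t_min[2] - tm$t_min[1]
                           else tm$t_max[1] - tm$t_min[1]),
    model = unclass(config$model),
    run = unclass(config$run))
  y$model <- y$model[!vapply(y$model, is.null, logical(1))]
  y$run <- y$run[!vapply(y$run, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

# ---- chain archive ----------------------------------------------------------

#' Save a chain to a plain-text archive
#'
#' Writes, under `dir`: `meta.json` (seed, bookkeeping, acceptance rates),
#' `config.yaml`, `scalars.csv` (per retained sample: log posterior, active
#' count, D), `params.csv` (per sample and frame: h, F), `loads.csv`,
#' `tracks.csv` (per sample, model emitter and sub-exposure index) and
#' `final_state.csv` (the last state, for resuming with
#' `run_chain(init = )`).
#'
#' @param chain A [run_chain()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_chain <- function(chain, dir) {
  stopifnot(inherits(chain, "jt_chain"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = chain$seed, iterations = chain$iterations,
               burn_in = chain$burn_in, thin = chain$thin,
               prior_only = chain$prior_only,
               n_samples = length(chain$samples),
               acceptance = as.list(chain$acceptance))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  write_config(chain$config, file.path(dir, "config.yaml"))
  utils::write.csv(data.frame(sample = seq_along(chain$samples),
                              log_post = chain$log_post, B = chain$B,
                              D = chain$D),
                   file.path(dir, "scalars.csv"), row.names = FALSE)
  N <- chain$config$timing$n_frames
  params <- do.call(rbind, lapply(seq_along(chain$samples), function(i) {
    s <- chain$samples[[i]]
    data.frame(sample = i, frame = seq_len(N), h = rep_len(s$h, N),
               F = rep_len(s$F, N))
  }))
  utils::write.csv(params, file.path(dir, "params.csv"), row.names = FALSE)
  loads <- do.call(rbind, lapply(seq_along(chain$samples), function(i)
    data.frame(sample = i, emitter = seq_along(chain$samples[[i]]$b),
               b = chain$samples[[i]]$b)))
  utils::write.csv(loads, file.path(dir, "loads.csv"), row.names = FALSE)
  tracks <- do.call(rbind, lapply(seq_along(chain$samples), function(i) {
    s <- chain$samples[[i]]
    S <- ncol(s$x)
    data.frame(sample = i,
               emitter = rep(seq_len(s$M), each = S),
               t_index = rep(seq_len(S), times = s$M),
               x = as.numeric(t(s$x)), y = as.numeric(t(s$y)),
               z = as.numeric(t(s$z)))
  }))
  utils::write.csv(tracks, file.path(dir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(chain$trace, file.path(dir, "trace.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a chain archive
#'
#' Reconstructs a [run_chain()]-style object (samples, log posteriors,
#' config) from a [save_chain()] directory; `chain$samples[[n_samples]]` can
#' seed `run_chain(init = )` to resume.
#'
#' @param dir Archive directory.
#' @return A `jt_chain`.
#' @export
load_chain <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  config <- read_config(file.path(dir, "config.yaml"))
  scalars <- utils::read.csv(file.path(dir, "scalars.csv"))
  params <- utils::read.csv(file.path(dir, "params.csv"))
  loads <- utils::read.csv(file.path(dir, "loads.csv"))
  tracks <- utils::read.csv(file.path(dir, "tracks.csv"))
  trace <- utils::read.csv(file.path(dir, "trace.csv"))
  samples <- lapply(seq_len(meta$n_samples), function(i) {
    b <- loads$b[loads$sample == i]
    tr <- tracks[tracks$sample == i, ]
    M <- length(b)
    S <- nrow(tr) / M
    x <- matrix(tr$x, nrow = M, byrow = TRUE)
    y <- matrix(tr$y, nrow = M, byrow = TRUE)
    z <- matrix(tr$z, nrow = M, byrow = TRUE)
    pp <- params[params$sample == i, ]
    system_state(b = b, x = x, y = y, z = z, D = scalars$D[i],
                 h = pp$h, F = pp$F)
  })
  structure(list(samples = samples, log_post = scalars$log_post,
                 B = as.integer(scalars$B), D = scalars$D, trace = trace,
                 acceptance = unlist(meta$acceptance), seed = meta$seed,
                 iterations = meta$iterations, burn_in = meta$burn_in,
                 thin = meta$thin, prior_only = isTRUE(meta$prior_only),
                 config = config),
            class = "jt_chain")
}
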