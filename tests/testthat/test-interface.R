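test_that("TIFF stacks round-trip through write and read", {
  cfg <- test_config(n_px = 10, n_frames = 5, K = 2)
  sc <- scenario(cfg, motion = "brownian", D = 1e4, B_true = 1, seed = 12,
                 starts = matrix(c(665, 665, 0), 1))
  stack <- render_stack(simulate_tracks(sc))$stack
  path <- tempfile(fileext = ".tif")
  write_stack(stack, path)
  back <- read_stack(path, cfg$camera, cfg$timing)
  expect_equal(back$values, round(stack$values), tolerance = 1e-12)
  expect_equal(dim(back$values)[3], 5L)
  # shape mismatches are reported
  wrong_cam <- test_camera(n_px = 8)
  expect_error(read_stack(path, wrong_cam, cfg$timing), "8 x 8")
  wrong_tm <- test_timing(n_frames = 4)
  expect_error(read_stack(path, cfg$camera, wrong_tm), "4")
})

test_that("track CSV round-trips and reports |z|", {
  N <- 6
  set.seed(77)
  m1 <- cbind(runif(N, 0, 2000), runif(N, 0, 2000), runif(N, -500, 500))
  m2 <- cbind(runif(N, 0, 2000), runif(N, 0, 2000), runif(N, -500, 500))
  ts <- ts_from_mats(list(m1, m2))
  path <- tempfile(fileext = ".csv")
  write_tracks(ts, path, timing = test_timing(N))
  df <- utils::read.csv(path)
  expect_true(all(df$abs_z_nm >= 0))
  expect_equal(sort(unique(df$t_seconds))[1], 0.05)
  back <- read_tracks(path, n_frames = N)
  expect_equal(n_tracks(back), 2L)
  ma <- jointtrack:::track_matrix(back, "t1")
  expect_equal(ma[, 1], m1[, 1], tolerance = 1e-6)
  expect_equal(ma[, 2], m1[, 2], tolerance = 1e-6)
  expect_equal(ma[, 3], abs(m1[, 3]), tolerance = 1e-6)
})

test_that("TrackMate XML has N spots, N-1 edges and round-trips", {
  N <- 7
  cam <- test_camera()
  m <- cbind(seq(100, 700, length.out = N), seq(200, 800, length.out = N),
             rep(150, N))
  ts <- ts_from_mats(list(m))
  path <- tempfile(fileext = ".xml")
  write_trackmate_xml(ts, path, cam)
  doc <- xml2::read_xml(path)
  expect_length(xml2::xml_find_all(doc, ".//Spot"), N)
  expect_length(xml2::xml_find_all(doc, ".//Edge"), N - 1)
  # positions in the file are in pixel units
  x_px <- as.numeric(xml2::xml_attr(xml2::xml_find_all(doc, ".//Spot"),
                                    "POSITION_X"))
  expect_true(all(x_px < 10))
  back <- read_trackmate_xml(path, cam, n_frames = N)
  mb <- jointtrack:::track_matrix(back, track_ids <- jointtrack:::track_ids(back)[1])
  expect_equal(mb[, 1], m[, 1], tolerance = 1e-6)
  expect_equal(mb[, 2], m[, 2], tolerance = 1e-6)
})

test_that("configuration files round-trip through YAML", {
  cfg <- test_config(n_px = 14, n_frames = 9, M = 8, K = 3, gamma = 2)
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$camera$pixel_size, cfg$camera$pixel_size)
  expect_equal(back$camera$n_rows, cfg$camera$n_rows)
  expect_equal(back$optics$sigma0, cfg$optics$sigma0)
  expect_equal(back$timing$t_min, cfg$timing$t_min)
  expect_equal(back$model$M, 8L)
  expect_equal(back$model$K, 3L)
  expect_equal(back$diffraction_limit, cfg$diffraction_limit)
})

test_that("chain archives round-trip and support resuming", {
  cfg <- validate_config(test_camera(10), test_optics(), test_timing(4),
                         model_config(M = 4, K = 2, gamma = 1.5),
                         run_config(iterations = 30, burn_in = 15, seed = 3))
  sc <- scenario(cfg, motion = "brownian", D = 1e4, B_true = 1, seed = 9,
                 starts = matrix(c(665, 665, 0), 1))
  stack <- render_stack(simulate_tracks(sc))$stack
  ch <- run_chain(stack, cfg)
  dir <- file.path(tempdir(), "chain-archive")
  save_chain(ch, dir)
  back <- load_chain(dir)
  expect_equal(back$log_post, ch$log_post, tolerance = 1e-9)
  expect_identical(back$B, ch$B)
  last <- back$samples[[length(back$samples)]]
  expect_equal(last$x, ch$samples[[length(ch$samples)]]$x, tolerance = 1e-9)
  # archived samples still reproduce their recorded log posterior
  i <- length(back$samples)
  expect_equal(state_log_posterior(back$samples[[i]], stack, cfg),
               back$log_post[i], tolerance = 1e-6)
  # resuming from the archived final state runs
  ch2 <- run_chain(stack, cfg, init = last)
  expect_s3_class(ch2, "jt_chain")
  unlink(dir, recursive = TRUE)
})

test_that("the CLI simulates, tracks and evaluates end to end", {
  out <- file.path(tempdir(), "cli-sim")
  unlink(out, recursive = TRUE)
  res <- cli_simulate("one-emitter", out)
  expect_true(file.exists(res$stack))
  expect_true(file.exists(res$truth_csv))
  expect_true(file.exists(res$manifest))
  man <- jsonlite::read_json(res$manifest)
  expect_equal(man$command, "simulate")
  expect_true(!is.null(man$config$camera$pixel_size))

  # identical estimate and reference: all metrics zero
  rep_path <- tempfile(fileext = ".json")
  suppressMessages(r <- cli_evaluate(res$truth_csv, res$truth_csv, rep_path))
  expect_equal(r$tracking_error_nm, 0)
  expect_equal(r$localization_resolution_nm, 0)
  expect_true(file.exists(rep_path))

  # track with a tiny chain on a reduced config, then score against truth
  cfg <- read_config(res$config)
  cfg$model <- model_config(M = 6, K = 4, gamma = 3)
  cfg$run <- run_config(iterations = 60, burn_in = 30, seed = 2,
                        background = "constant", estimate_brightness = FALSE,
                        fixed_h = 5000)
  cfg2 <- validate_config(cfg$camera, cfg$optics, cfg$timing, cfg$model, cfg$run)
  cfg_path <- tempfile(fileext = ".yaml")
  write_config(cfg2, cfg_path)
  trk_out <- file.path(tempdir(), "cli-trk")
  unlink(trk_out, recursive = TRUE)
  suppressMessages(tr <- cli_track(res$stack, cfg_path, trk_out))
  expect_true(file.exists(file.path(trk_out, "summary.json")))
  expect_true(file.exists(file.path(trk_out, "count_posterior.csv")))
  if (tr$estimate$B_map > 0) {
    rep2 <- tempfile(fileext = ".json")
    suppressMessages(r2 <- cli_evaluate(file.path(trk_out, "map_tracks.csv"),
                                        res$truth_csv, rep2, n_frames = 22))
    expect_lt(r2$tracking_error_nm, 665)
  }
  # determinism of the tracking outputs under a fixed seed
  trk_out2 <- file.path(tempdir(), "cli-trk2")
  unlink(trk_out2, recursive = TRUE)
  suppressMessages(tr2 <- cli_track(res$stack, cfg_path, trk_out2))
  expect_identical(tr$chain$log_post, tr2$chain$log_post)
  unlink(c(out, trk_out, trk_out2), recursive = TRUE)
})

test_that("cli_main dispatches and returns distinct exit codes", {
  expect_equal(suppressMessages(cli_main(character(0))), 2L)
  expect_equal(suppressMessages(cli_main(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(cli_main(c("evaluate", "--estimate", "a.csv"))), 1L)
  out <- file.path(tempdir(), "cli-main-sim")
  unlink(out, recursive = TRUE)
  expect_equal(suppressMessages(
    cli_main(c("simulate", "--fixture", "background-only", "--out", out))), 0L)
  expect_true(file.exists(file.path(out, "stack.tif")))
  unlink(out, recursive = TRUE)
})
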