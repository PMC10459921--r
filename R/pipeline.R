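# End-to-end orchestration: phantom dataset -> FPM simulate/reconstruct
# demo -> GAN augmentation -> detector training -> evaluation, driven by
# one config and one seed, with a run manifest recording inputs, outputs
# and checksums per stage.

default_pipeline_config <- function() {
  list(
    phantom = list(n_images = 8L, side = 128L, fov_um = 102.4,
                   n_rbc = c(35, 60), n_wbc = c(1, 5), overlap_prob = 0.2),
    optics = list(leds = 7L, na = 0.1, ratio = 4L,
                  wavelengths_um = list(red = 0.632, green = 0.532,
                                        blue = 0.470),
                  pitch_mm = 4, distance_mm = 80),
    recon = list(n_iters = 5L),
    gan = list(enabled = TRUE, base_channels = 64L, epochs = 5L,
               batch_size = 8L),
    detector = list(epochs = 5L, batch_size = 4L, num_queries = 25L,
                    hidden_dim = 64L, base_width = 16L,
                    backbone_variant = "resnet18", box_loss = "ciou"),
    split = list(train_fraction = 0.8)
  )
}

read_pipeline_config <- function(config_path) {
  cfg <- default_pipeline_config()
  if (is.null(config_path)) return(cfg)
  user <- if (grepl("\\.ya?ml$", config_path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package needed for YAML configs; use JSON instead")
    yaml::read_yaml(config_path)
  } else jsonlite::read_json(config_path, simplifyVector = TRUE)
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    for (key in names(user[[sec]])) cfg[[sec]][[key]] <- user[[sec]][[key]]
  }
  cfg
}

file_checksum <- function(path) {
  if (requireNamespace("digest", quietly = TRUE))
    digest::digest(path, file = TRUE, algo = "md5")
  else as.character(file.size(path))
}

#' Run the full workbench pipeline
#'
#' Stages, in order: `phantom` (scenes, rendered tiles, COCO ground
#' truth, train/test split), `simulate` (FPM stack of the first scene),
#' `reconstruct` (RGB reconstruction of that stack), `gan` (DCGAN on
#' white-cell crops + 1:1 augmentation), `train` (detector on the train
#' split), `evaluate` (mAP on train and held-out test split). Every
#' stochastic stage derives its stream from the single `seed`. Artifacts
#' and checksums are recorded in `manifest.json` under `out_dir`.
#'
#' @param config_path YAML or JSON config overriding the defaults
#'   (sections `phantom`, `optics`, `recon`, `gan`, `detector`, `split`);
#'   `NULL` for the built-in demo configuration.
#' @param seed master seed.
#' @param out_dir output directory.
#' @param stages subset of stages to run (dependencies are the caller's
#'   responsibility when resuming).
#' @param verbose log stage progress.
#' @returns the run manifest (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config_path = NULL, seed = 1L, out_dir = "fpm_run",
                         stages = c("phantom", "simulate", "reconstruct",
                                    "gan", "train", "evaluate"),
                         verbose = TRUE) {
  cfg <- read_pipeline_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = seed, config = cfg,
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list())
  record <- function(stage, outputs, extra = list()) {
    manifest$stages[[stage]] <<- c(list(
      outputs = lapply(outputs, function(p)
        list(path = p, checksum = file_checksum(p)))), extra)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  state <- new.env(parent = emptyenv())

  if ("phantom" %in% stages) tryCatch({
    say("stage phantom: %d tiles", cfg$phantom$n_images)
    pc <- detection_phantom_config(fov_um = cfg$phantom$fov_um,
                                   n_rbc = cfg$phantom$n_rbc,
                                   n_wbc = cfg$phantom$n_wbc,
                                   overlap_prob = cfg$phantom$overlap_prob)
    ds <- make_detection_dataset(cfg$phantom$n_images, cfg$phantom$side,
                                 pc, seed = seed * 1000L)
    pdir <- file.path(out_dir, "phantom")
    dir.create(pdir, showWarnings = FALSE)
    files <- character(0)
    for (i in seq_along(ds$images)) {
      p <- file.path(pdir, sprintf("tile_%03d.ppm", i))
      write_ppm(ds$images[[i]], p)
      files <- c(files, p)
    }
    coco <- file.path(pdir, "annotations.json")
    write_coco(ds$annotations, coco,
               file_names = sprintf("tile_%03d.ppm", seq_along(ds$images)))
    n <- length(ds$images)
    set.seed(seed + 1L)
    n_train <- round(cfg$split$train_fraction * n)
    train_idx <- sort(sample.int(n, n_train))
    split <- list(train = train_idx, test = setdiff(seq_len(n), train_idx))
    split_path <- file.path(pdir, "split.json")
    jsonlite::write_json(split, split_path, pretty = TRUE)
    state$ds <- ds; state$split <- split
    record("phantom", c(files, coco, split_path),
           list(n_train = length(split$train), n_test = length(split$test)))
  }, error = function(e) fail("phantom", e))

  if ("simulate" %in% stages) tryCatch({
    say("stage simulate: %dx%d LEDs, 3 channels", cfg$optics$leds, cfg$optics$leds)
    sc <- state$ds$scenes[[1]]
    side_hi <- cfg$phantom$side * cfg$optics$ratio
    fields <- lapply(stats::setNames(nm = c("red", "green", "blue")),
                     function(ch) render_highres(sc, side_hi, ch))
    arr <- led_array(cfg$optics$leds, cfg$optics$leds,
                     pitch_mm = cfg$optics$pitch_mm,
                     distance_mm = cfg$optics$distance_mm,
                     wavelengths_um = unlist(cfg$optics$wavelengths_um))
    st <- simulate_stack(fields, arr, na = cfg$optics$na,
                         ratio = cfg$optics$ratio)
    sdir <- file.path(out_dir, "stack")
    write_stack(st, sdir)
    state$stack <- st
    record("simulate", file.path(sdir, "manifest.json"),
           list(n_frames = length(st$frames)))
  }, error = function(e) fail("simulate", e))

  if ("reconstruct" %in% stages) tryCatch({
    say("stage reconstruct: %d iterations", cfg$recon$n_iters)
    rec <- reconstruct_rgb(state$stack, n_iters = cfg$recon$n_iters)
    rdir <- file.path(out_dir, "recon")
    dir.create(rdir, showWarnings = FALSE)
    rgb_path <- file.path(rdir, "recon_rgb.ppm")
    write_ppm(rec$rgb, rgb_path)
    conv_path <- file.path(rdir, "convergence.json")
    jsonlite::write_json(
      lapply(rec$per_channel, function(r) r$convergence_trace),
      conv_path, digits = NA, pretty = TRUE)
    record("reconstruct", c(rgb_path, conv_path))
  }, error = function(e) fail("reconstruct", e))

  if ("gan" %in% stages && isTRUE(cfg$gan$enabled)) tryCatch({
    crops <- extract_wbc_crops(state$ds, max_crops = 64L)
    say("stage gan: %d crops, %d epochs", length(crops), cfg$gan$epochs)
    gdir <- file.path(out_dir, "gan")
    dir.create(gdir, showWarnings = FALSE)
    if (length(crops) > 0) {
      gcfg <- gan_config(base_channels = cfg$gan$base_channels,
                         batch_size = cfg$gan$batch_size,
                         epochs = cfg$gan$epochs, seed = seed + 2L)
      gan <- train_dcgan(lapply(crops, function(cr) cr * 2 - 1), gcfg)
      aug <- augment_dataset(crops, gan, seed = seed + 3L)
      files <- character(0)
      for (i in seq_along(aug)) {
        p <- file.path(gdir, sprintf("crop_%03d_%s.ppm", i,
                                     aug[[i]]$provenance))
        write_ppm(aug[[i]]$image, p)
        files <- c(files, p)
      }
      loss_path <- file.path(gdir, "gan_losses.json")
      jsonlite::write_json(gan$losses, loss_path, digits = NA, pretty = TRUE)
      state$aug <- aug
      record("gan", c(files, loss_path),
             list(n_real = length(crops), n_total = length(aug)))
    } else record("gan", character(0), list(n_real = 0L, n_total = 0L))
  }, error = function(e) fail("gan", e))

  if ("train" %in% stages) tryCatch({
    say("stage train: %d epochs on %d tiles", cfg$detector$epochs,
        length(state$split$train))
    dcfg <- detector_config(
      num_queries = cfg$detector$num_queries,
      hidden_dim = cfg$detector$hidden_dim,
      base_width = cfg$detector$base_width,
      backbone_variant = cfg$detector$backbone_variant,
      box_loss = cfg$detector$box_loss,
      image_side = cfg$phantom$side)
    tr <- train_detector(state$ds$images[state$split$train],
                         state$ds$targets[state$split$train],
                         dcfg, epochs = cfg$detector$epochs,
                         batch_size = cfg$detector$batch_size,
                         seed = seed + 4L)
    state$model <- tr$model
    tdir <- file.path(out_dir, "detector")
    dir.create(tdir, showWarnings = FALSE)
    hist_path <- file.path(tdir, "history.json")
    jsonlite::write_json(tr$history, hist_path, digits = NA, pretty = TRUE)
    record("train", hist_path)
  }, error = function(e) fail("train", e))

  if ("evaluate" %in% stages) tryCatch({
    train_map <- dataset_map(state$model, state$ds$images[state$split$train],
                             state$ds$targets[state$split$train])
    test_map <- if (length(state$split$test) > 0)
      dataset_map(state$model, state$ds$images[state$split$test],
                  state$ds$targets[state$split$test]) else NA_real_
    say("stage evaluate: train mAP %.3f, test mAP %.3f", train_map, test_map)
    edir <- file.path(out_dir, "eval")
    dir.create(edir, showWarnings = FALSE)
    mpath <- file.path(edir, "metrics.json")
    jsonlite::write_json(list(train_map = train_map, test_map = test_map),
                         mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    record("evaluate", mpath,
           list(train_map = train_map, test_map = test_map))
  }, error = function(e) fail("evaluate", e))

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

# 64x64 white-cell crops (RGB, [0, 1]) cut from dataset tiles
extract_wbc_crops <- function(ds, max_crops = 64L, crop = 64L) {
  crops <- list()
  for (i in seq_along(ds$images)) {
    img <- ds$images[[i]]
    side <- dim(img)[1]
    bx <- ds$annotations[[i]]$boxes
    for (j in seq_len(nrow(bx))) {
      cx <- round(bx$x[j] + bx$w[j] / 2); cy <- round(bx$y[j] + bx$h[j] / 2)
      x0 <- min(max(cx - crop / 2 + 1, 1), side - crop + 1)
      y0 <- min(max(cy - crop / 2 + 1, 1), side - crop + 1)
      crops[[length(crops) + 1]] <-
        img[y0:(y0 + crop - 1), x0:(x0 + crop - 1), , drop = FALSE]
      if (length(crops) >= max_crops) return(crops)
    }
  }
  crops
}
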