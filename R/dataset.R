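# Detection datasets from phantom scenes: rendered RGB tiles plus
# normalized ground-truth boxes, with the COCO annotation set alongside.

#' Normalized center-format box matrix from an annotation set
#'
#' @param ann an [scene_to_annotations()] result.
#' @returns `n x 4` matrix (cx, cy, w, h) in `[0, 1]`.
#' @export
annotations_to_norm <- function(ann) {
  b <- ann$boxes
  if (nrow(b) == 0) return(matrix(numeric(0), 0, 4))
  s <- ann$image_side
  cbind((b$x + b$w / 2) / s, (b$y + b$h / 2) / s, b$w / s, b$h / s)
}

#' Build a detection dataset of phantom tiles
#'
#' Generates `n_images` scenes from `config`, renders each as an RGB tile
#' and derives the white-cell ground truth. Two imaging routes: `"ideal"`
#' renders the squared-magnitude color image directly from the phantom (a
#' perfect wide-field reconstruction; fast), `"fpm"` runs the full
#' simulate-then-reconstruct pipeline per tile (slow; used by the
#' end-to-end pipeline demo).
#'
#' @param n_images number of tiles.
#' @param side tile side, pixels.
#' @param config a [phantom_config()]; default [detection_phantom_config()].
#' @param seed base seed; scene i uses `seed + i`.
#' @param imaging `"ideal"` or `"fpm"`.
#' @param fpm_opts list of options for the `"fpm"` route: `leds` (LED
#'   array side, default 7), `na`, `ratio`, `n_iters`.
#' @returns list with `images` (list of side x side x 3 arrays),
#'   `targets` (list of normalized box matrices), `annotations` (list of
#'   annotation sets), `scenes`.
#' @export
make_detection_dataset <- function(n_images, side = 128L,
                                   config = detection_phantom_config(),
                                   seed = 1L, imaging = c("ideal", "fpm"),
                                   fpm_opts = list()) {
  imaging <- match.arg(imaging)
  images <- targets <- anns <- scenes <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sc <- generate_scene(config, seed = seed + i)
    img <- if (imaging == "ideal") {
      render_color_image(sc, side)
    } else {
      leds <- fpm_opts$leds %||% 7L
      na <- fpm_opts$na %||% 0.1
      ratio <- fpm_opts$ratio %||% 4L
      iters <- fpm_opts$n_iters %||% 8L
      fields <- lapply(stats::setNames(nm = c("red", "green", "blue")),
                       function(ch) render_highres(sc, side * ratio, ch))
      st <- simulate_stack(fields, led_array(leds, leds), na = na, ratio = ratio)
      rec <- reconstruct_rgb(st, n_iters = iters)
      # reconstruction is amplitude; square for intensity to match "ideal"
      img <- rec$rgb^2
      img
    }
    ann <- scene_to_annotations(sc, side, image_id = i)
    images[[i]] <- img
    targets[[i]] <- annotations_to_norm(ann)
    anns[[i]] <- ann
    scenes[[i]] <- sc
  }
  list(images = images, targets = targets, annotations = anns, scenes = scenes)
}

#' Training-set mAP of a detector
#'
#' Runs [forward_detect()] on every image and scores all queries against
#' the ground truth with [evaluate_map()].
#'
#' @param model detector.
#' @param images,targets as in [train_detector()].
#' @param iou_threshold mAP matching threshold.
#' @param score_min drop predictions below this confidence (default keeps
#'   all; ranking handles the rest).
#' @export
dataset_map <- function(model, images, targets, iou_threshold = 0.5,
                        score_min = 0) {
  preds <- NULL; gt <- NULL
  for (i in seq_along(images)) {
    p <- forward_detect(images[[i]], model)
    p$image_id <- i
    preds <- rbind(preds, p[p$score >= score_min, , drop = FALSE])
    tg <- targets[[i]]
    if (nrow(tg) > 0)
      gt <- rbind(gt, data.frame(image_id = i, cx = tg[, 1], cy = tg[, 2],
                                 w = tg[, 3], h = tg[, 4]))
  }
  evaluate_map(preds, gt, iou_threshold)
}
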