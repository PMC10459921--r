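# Plain-text image and annotation I/O: ASCII PGM/PPM for frames and RGB
# composites (no binary dependencies), a JSON frame manifest for
# acquisition stacks, and COCO-style annotation JSON.

#' Write / read an ASCII PGM (grayscale) image
#'
#' P2 format with a 16-bit range. Values are scaled by `scale` and
#' rounded; `read_pgm` returns the integer matrix divided by `scale`.
#'
#' @param img numeric matrix (rows = image rows).
#' @param path file path.
#' @param scale divisor mapping stored integers back to data units;
#'   default maps `maxval` to the matrix maximum.
#' @returns `write_pgm` the scale used (invisibly); `read_pgm` a matrix
#'   with attribute `scale`.
#' @export
write_pgm <- function(img, path, scale = NULL) {
  maxval <- 65535L
  if (is.null(scale))
    scale <- if (max(img) > 0) maxval / max(img) else 1
  q <- pmin(pmax(round(img * scale), 0L), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  write(t(q), file = con, ncolumns = ncol(img))
  invisible(scale)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path, scale = 1) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count in ", path)
  out <- matrix(vals, nrow = h, ncol = w, byrow = TRUE) / scale
  attr(out, "scale") <- scale
  out
}

#' Write an RGB array as ASCII PPM
#'
#' @param img `(H, W, 3)` array in `[0, 1]`.
#' @param path file path.
#' @export
write_ppm <- function(img, path) {
  maxval <- 255L
  q <- pmin(pmax(round(img * maxval), 0L), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(dim(img)[2], dim(img)[1]), as.character(maxval)), con)
  # interleave channels row-major
  inter <- matrix(0L, nrow(q) , ncol(q) * 3)
  inter[, seq(1, ncol(inter), 3)] <- q[, , 1]
  inter[, seq(2, ncol(inter), 3)] <- q[, , 2]
  inter[, seq(3, ncol(inter), 3)] <- q[, , 3]
  write(t(inter), file = con, ncolumns = min(15, ncol(inter)))
  invisible(path)
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P3") stop("not an ASCII PPM (P3) file: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)]) / mx
  if (length(vals) != 3 * w * h) stop("corrupt PPM: wrong pixel count")
  inter <- matrix(vals, nrow = h, byrow = TRUE)
  out <- array(0, c(h, w, 3))
  for (c in 1:3) out[, , c] <- inter[, seq(c, ncol(inter), 3)]
  out
}

#' Write an acquisition stack to a directory
#'
#' One ASCII PGM per frame plus `manifest.json` recording the geometry
#' and, per frame, the LED position, channel, wavelength, illumination
#' wave vector and intensity scale, so the acquisition convention is
#' re-derivable from the files alone.
#'
#' @param stack an [simulate_stack()] result.
#' @param dir output directory (created if needed).
#' @returns the manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- vector("list", length(stack$frames))
  for (i in seq_along(stack$frames)) {
    f <- stack$frames[[i]]
    file <- sprintf("frame_%04d.pgm", i)
    scale <- write_pgm(f$intensity, file.path(dir, file))
    frames[[i]] <- list(file = file, led_row = f$led_row, led_col = f$led_col,
                        channel = f$channel, wavelength_um = f$wavelength_um,
                        kx = f$kx, ky = f$ky, scale = scale)
  }
  manifest <- list(
    lowres_side = stack$lowres_side, ratio = stack$ratio,
    highres_side = stack$highres_side, pixel_pitch_um = stack$pixel_pitch_um,
    na = stack$na, channels = as.list(stack$channels),
    array = list(rows = stack$array$rows, cols = stack$array$cols,
                 pitch_mm = stack$array$pitch_mm,
                 distance_mm = stack$array$distance_mm,
                 center_offset_mm = stack$array$center_offset_mm,
                 wavelengths_um = as.list(stack$array$wavelengths_um)),
    frames = frames)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  m <- jsonlite::read_json(path)
  arr <- led_array(m$array$rows, m$array$cols, m$array$pitch_mm,
                   m$array$distance_mm, unlist(m$array$center_offset_mm),
                   unlist(m$array$wavelengths_um))
  frames <- lapply(m$frames, function(fr) {
    int <- read_pgm(file.path(dir, fr$file), scale = fr$scale)
    attr(int, "scale") <- NULL
    list(intensity = int, led_row = fr$led_row, led_col = fr$led_col,
         led_index = (fr$led_row - 1L) * arr$cols + fr$led_col,
         channel = fr$channel, wavelength_um = fr$wavelength_um,
         kx = fr$kx, ky = fr$ky)
  })
  structure(list(frames = frames, lowres_side = m$lowres_side,
                 ratio = m$ratio, highres_side = m$highres_side,
                 pixel_pitch_um = m$pixel_pitch_um, na = m$na,
                 array = arr, channels = unlist(m$channels)),
            class = "fpm_stack")
}

#' Write annotation sets as COCO JSON
#'
#' Standard COCO layout: `images`, `annotations` with `[x, y, w, h]`
#' pixel boxes (top-left origin, 0-based), `categories` with the single
#' foreground class.
#'
#' @param anns one [scene_to_annotations()] result or a list of them.
#' @param path output path.
#' @param file_names optional per-image file names.
#' @export
write_coco <- function(anns, path, file_names = NULL) {
  if (inherits(anns, "annotation_set")) anns <- list(anns)
  images <- list(); annotations <- list(); aid <- 0L
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    images[[i]] <- list(id = a$image_id,
                        width = a$image_side, height = a$image_side,
                        file_name = if (is.null(file_names)) ""
                                    else file_names[[i]])
    bx <- a$boxes
    for (j in seq_len(nrow(bx))) {
      aid <- aid + 1L
      annotations[[aid]] <- list(
        id = aid, image_id = a$image_id, category_id = 1L,
        bbox = c(bx$x[j], bx$y[j], bx$w[j], bx$h[j]),
        area = bx$w[j] * bx$h[j], iscrowd = 0L)
    }
  }
  obj <- list(images = images, annotations = annotations,
              categories = list(list(id = 1L, name = "wbc")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_coco
#' @export
read_coco <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed COCO JSON at ", path,
                                           ": ", conditionMessage(e)))
  for (field in c("images", "annotations", "categories"))
    if (is.null(obj[[field]]))
      stop("malformed COCO JSON: missing field '", field, "'")
  out <- vector("list", length(obj$images))
  for (i in seq_along(obj$images)) {
    im <- obj$images[[i]]
    if (is.null(im$id) || is.null(im$width))
      stop("malformed COCO JSON: images[", i, "] lacks id/width")
    rows <- Filter(function(a) identical(a$image_id, im$id), obj$annotations)
    boxes <- if (length(rows) == 0) {
      data.frame(x = numeric(), y = numeric(), w = numeric(), h = numeric(),
                 label = character(), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(rows, function(a) {
        if (length(a$bbox) != 4)
          stop("malformed COCO JSON: annotations id ", a$id, " bbox length")
        data.frame(x = a$bbox[[1]], y = a$bbox[[2]], w = a$bbox[[3]],
                   h = a$bbox[[4]], label = "wbc", stringsAsFactors = FALSE)
      }))
    }
    out[[i]] <- structure(list(boxes = boxes, image_side = im$width,
                               image_id = im$id), class = "annotation_set")
  }
  out
}
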