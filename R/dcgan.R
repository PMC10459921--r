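# DCGAN for cell-crop augmentation: the generator maps a latent vector
# through a fully connected layer to a 4 x 4 x 1024 feature map and four
# transposed-convolution stages (channels halving 1024 -> 512 -> 256 ->
# 128 -> 3) to a 64 x 64 x 3 image in [-1, 1]; the discriminator mirrors
# it with strided convolutions down to a single realness score.

#' DCGAN configuration
#'
#' @param latent_dim latent-vector length.
#' @param base_channels channels of the 4x4 feature map (1024 for the
#'   full architecture; reduce for fast smoke training).
#' @param image_side output side; fixed to `4 * 2^4 = 64` by the
#'   four-stage design.
#' @param lr,beta1 Adam settings (DCGAN convention 2e-4, 0.5).
#' @param batch_size minibatch size.
#' @param epochs training epochs over the crop set (300 in the stated
#'   augmentation protocol; smoke tests use far fewer).
#' @param seed RNG seed.
#' @export
gan_config <- function(latent_dim = 100L, base_channels = 1024L,
                       image_side = 64L, lr = 2e-4, beta1 = 0.5,
                       batch_size = 64L, epochs = 300L, seed = 1L) {
  if (image_side != 64L)
    stop("the four-stage generator fixes image_side = 64")
  if (base_channels %% 8 != 0) stop("base_channels must be divisible by 8")
  as.list(environment())
}

#' Build the DCGAN generator
#'
#' latent -> fully connected -> 4x4x`base` -> four transposed convs
#' (kernel 4, stride 2, pad 1) halving channels to a 64x64x3 tanh output.
#'
#' @param cfg a [gan_config()].
#' @param seed weight-init seed.
#' @returns layer object; forward input is an `(N, latent_dim)` matrix.
#' @export
build_generator <- function(cfg = gan_config(), seed = cfg$seed) {
  set.seed(seed)
  b <- cfg$base_channels
  fc <- nn_linear(cfg$latent_dim, 4L * 4L * b, init_sd = 0.02)
  stages <- nn_sequential(
    nn_batchnorm2d(b), nn_relu(),
    nn_conv_transpose2d(b, b %/% 2L, 4L, 2L, 1L, init_sd = 0.02),
    nn_batchnorm2d(b %/% 2L), nn_relu(),
    nn_conv_transpose2d(b %/% 2L, b %/% 4L, 4L, 2L, 1L, init_sd = 0.02),
    nn_batchnorm2d(b %/% 4L), nn_relu(),
    nn_conv_transpose2d(b %/% 4L, b %/% 8L, 4L, 2L, 1L, init_sd = 0.02),
    nn_batchnorm2d(b %/% 8L), nn_relu(),
    nn_conv_transpose2d(b %/% 8L, 3L, 4L, 2L, 1L, init_sd = 0.02),
    nn_layer(function(x, training, self) ag_tanh(x),
             extra = list(kind = "tanh")))
  nn_layer(function(z, training, self) {
    n <- nrow(ag_value(z))
    x <- nn_forward(self$children$fc, z, training)
    x <- ag_reshape(ag_transpose(x), c(4L, 4L, cfg$base_channels, n))
    nn_forward(self$children$stages, x, training)
  }, children = list(fc = fc, stages = stages),
  extra = list(kind = "generator", cfg = cfg))
}

#' Build the DCGAN discriminator
#'
#' 64x64x3 -> four stride-2 convolutions (channels `base/8` doubling to
#' `base`) -> fully connected -> sigmoid realness score in (0, 1).
#'
#' @inheritParams build_generator
#' @export
build_discriminator <- function(cfg = gan_config(), seed = cfg$seed + 1L) {
  set.seed(seed)
  b <- cfg$base_channels
  body <- nn_sequential(
    nn_conv2d(3L, b %/% 8L, 4L, 2L, 1L, init_sd = 0.02), nn_leaky_relu(0.2),
    nn_conv2d(b %/% 8L, b %/% 4L, 4L, 2L, 1L, init_sd = 0.02),
    nn_batchnorm2d(b %/% 4L), nn_leaky_relu(0.2),
    nn_conv2d(b %/% 4L, b %/% 2L, 4L, 2L, 1L, init_sd = 0.02),
    nn_batchnorm2d(b %/% 2L), nn_leaky_relu(0.2),
    nn_conv2d(b %/% 2L, b, 4L, 2L, 1L, init_sd = 0.02),
    nn_batchnorm2d(b), nn_leaky_relu(0.2))
  head <- nn_linear(4L * 4L * b, 1L, init_sd = 0.02)
  nn_layer(function(x, training, self) {
    h <- nn_forward(self$children$body, x, training)
    n <- dim(ag_value(h))[4]
    hm <- ag_transpose(ag_reshape(h, c(length(ag_value(h)) %/% n, n)))
    ag_sigmoid(nn_forward(self$children$head, hm, training))
  }, children = list(body = body, head = head),
  extra = list(kind = "discriminator", cfg = cfg))
}

#' Trace the generator's per-stage output shapes
#'
#' Runs one latent vector through the generator and records the shape
#' after the fully connected reshape and after every upsampling stage.
#'
#' @param gen a [build_generator()] model (or a [gan_config()], from
#'   which a generator is built).
#' @returns list of integer vectors `(H, W, C)` from the 4x4 feature map
#'   to the final image.
#' @export
generator_shape_trace <- function(gen = gan_config()) {
  if (!inherits(gen, "nn_layer")) gen <- build_generator(gen)
  cfg <- gen$cfg
  z <- matrix(stats::rnorm(cfg$latent_dim), 1)
  shapes <- list()
  ag_no_grad({
    x <- nn_forward(gen$children$fc, ag_const(z), FALSE)
    x <- ag_reshape(ag_transpose(x), c(4L, 4L, cfg$base_channels, 1L))
    shapes[[1]] <- dim(x$v)[1:3]
    for (l in gen$children$stages$children) {
      x <- nn_forward(l, x, FALSE)
      if (identical(l$kind, "conv_transpose2d") || identical(l$kind, "tanh"))
        shapes[[length(shapes) + 1]] <- dim(x$v)[1:3]
    }
  })
  # drop the duplicate shape after tanh (same as last conv-transpose)
  shapes[!duplicated(vapply(shapes, paste, "", collapse = "x"))]
}

#' Sample images from the generator
#'
#' @param gen generator.
#' @param n number of samples.
#' @param seed latent seed; `NULL` uses the current RNG state.
#' @returns `(64, 64, 3, n)` array in `[-1, 1]`.
#' @export
gan_sample <- function(gen, n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * gen$cfg$latent_dim), n)
  ag_no_grad(nn_forward(gen, ag_const(z), FALSE))$v
}

bce <- function(p, y) -mean(y * log(pmax(p, 1e-8)) + (1 - y) * log(pmax(1 - p, 1e-8)))

ag_bce <- function(p, y) {
  p <- as_node(p)
  v <- bce(p$v, y)
  n <- length(p$v)
  new_node(v, list(p), function(g)
    list(as.numeric(g) * (-(y / pmax(p$v, 1e-8)) +
                            (1 - y) / pmax(1 - p$v, 1e-8)) / n))
}

#' Train the DCGAN on cell crops
#'
#' Alternating discriminator/generator updates with the standard
#' adversarial (binary cross-entropy) objective and Adam (`beta1` 0.5).
#' Fully seeded: identical seeds give identical runs.
#'
#' @param crops `(64, 64, 3, N)` array in `[-1, 1]`, or a list of
#'   `(64, 64, 3)` arrays.
#' @param cfg a [gan_config()].
#' @param epochs override `cfg$epochs`.
#' @param verbose print per-epoch losses?
#' @returns list `generator`, `discriminator`, `losses` (data.frame per
#'   epoch: `d_loss`, `g_loss`), `cfg`.
#' @export
train_dcgan <- function(crops, cfg = gan_config(), epochs = cfg$epochs,
                        verbose = FALSE) {
  if (is.list(crops)) {
    stopifnot(length(crops) >= 1)
    arr <- array(0, c(64, 64, 3, length(crops)))
    for (i in seq_along(crops)) arr[, , , i] <- crops[[i]]
    crops <- arr
  }
  n <- dim(crops)[4]
  if (n < 1) stop("empty crop set")
  set.seed(cfg$seed)
  gen <- build_generator(cfg, seed = cfg$seed)
  dis <- build_discriminator(cfg, seed = cfg$seed + 1L)
  gp <- collect_params(gen); dp <- collect_params(dis)
  opt_g <- adamw(gp, lr = cfg$lr, beta1 = cfg$beta1, weight_decay = 0)
  opt_d <- adamw(dp, lr = cfg$lr, beta1 = cfg$beta1, weight_decay = 0)
  bs <- min(cfg$batch_size, n)
  losses <- data.frame(epoch = integer(), d_loss = numeric(), g_loss = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    dl <- gl <- 0; nb <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      real <- crops[, , , idx, drop = FALSE]
      m <- length(idx)
      z <- matrix(stats::rnorm(m * cfg$latent_dim), m)
      # discriminator step
      ag_begin()
      fake <- nn_forward(gen, ag_const(z), TRUE)
      d_real <- nn_forward(dis, ag_const(real), TRUE)
      d_fake <- nn_forward(dis, ag_const(fake$v), TRUE)   # detached
      d_loss <- ag_add(ag_bce(d_real, 1), ag_bce(d_fake, 0))
      zero_grads(dp); ag_backward(d_loss); adamw_step(opt_d)
      dlv <- as.numeric(d_loss$v)
      ag_end()
      # generator step (fresh graph through D)
      ag_begin()
      fake <- nn_forward(gen, ag_const(z), TRUE)
      g_loss <- ag_bce(nn_forward(dis, fake, TRUE), 1)
      zero_grads(c(gp, dp)); ag_backward(g_loss)
      zero_grads(dp)                       # only G updates here
      adamw_step(opt_g)
      glv <- as.numeric(g_loss$v)
      ag_end()
      dl <- dl + dlv; gl <- gl + glv; nb <- nb + 1
    }
    losses <- rbind(losses, data.frame(epoch = ep, d_loss = dl / nb,
                                       g_loss = gl / nb))
    if (verbose)
      message(sprintf("gan epoch %3d  D %.4f  G %.4f", ep, dl / nb, gl / nb))
  }
  list(generator = gen, discriminator = dis, losses = losses, cfg = cfg,
       trained = TRUE)
}

#' Expand a crop dataset 1:1 with generated samples
#'
#' Emits exactly one synthetic white-cell crop per real crop (doubling
#' the set), compositing each generated 64x64 patch onto a red-cell-only
#' phantom background tile with a radial blend, and tagging every
#' synthetic item with `provenance = "generated"`. Real items are passed
#' through untouched.
#'
#' @param real_crops list of `(64, 64, 3)` arrays in `[0, 1]` (with
#'   optional `box` attribute) or items as returned by this function.
#' @param gan a [train_dcgan()] result (must be trained).
#' @param seed seed for latents and backgrounds.
#' @returns list of items: `image` (64x64x3, `[0, 1]`), `box`
#'   (normalized [bbox()] of the cell), `provenance` (`"real"` or
#'   `"generated"`).
#' @export
augment_dataset <- function(real_crops, gan, seed = 1L) {
  if (is.null(gan$trained) || !isTRUE(gan$trained))
    stop("generator is untrained; train_dcgan() must be run first")
  n <- length(real_crops)
  if (n == 0) return(list())
  set.seed(seed)
  items <- vector("list", 2L * n)
  default_box <- bbox(0.5, 0.5, 0.75, 0.75)
  for (i in seq_len(n)) {
    rc <- real_crops[[i]]
    img <- if (is.list(rc)) rc$image else rc
    bx <- if (is.list(rc) && !is.null(rc$box)) rc$box
          else attr(rc, "box") %||% default_box
    items[[i]] <- list(image = img, box = bx, provenance = "real")
  }
  gen_imgs <- gan_sample(gan$generator, n)
  # radial blend mask for compositing onto background tiles
  gcoord <- (seq_len(64) - 32.5) / 32
  rad <- sqrt(outer(gcoord^2, gcoord^2, `+`))
  blend <- pmin(pmax((1 - rad) / 0.25, 0), 1)
  for (i in seq_len(n)) {
    bg_scene <- generate_scene(
      detection_phantom_config(fov_um = 25.6, n_rbc = c(1, 3), n_wbc = 0,
                               overlap_prob = 0),
      seed = seed + 1000L + i)
    bg <- render_color_image(bg_scene, 64)
    syn <- (gen_imgs[, , , i] + 1) / 2
    out <- array(0, c(64, 64, 3))
    for (c in 1:3) out[, , c] <- blend * syn[, , c] + (1 - blend) * bg[, , c]
    items[[n + i]] <- list(image = out, box = default_box,
                           provenance = "generated")
  }
  items
}
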