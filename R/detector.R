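# Set-prediction white-cell detector: ResNet-style backbone whose
# downsampling residual blocks use an average-pool shortcut (3x3 conv
# stride 2 on the main path) to avoid the information loss of a 1x1
# stride-2 convolution, a transformer encoder-decoder over image tokens
# with sinusoidal positional encoding, FFN class/box heads, Hungarian
# matching, and a combined CIOU + L1 border loss.

#' Residual block specification
#'
#' @param in_channels,mid_channels,out_channels channel counts; for
#'   bottleneck blocks `out_channels = 4 * mid_channels`.
#' @param downsample halve the spatial side?
#' @export
conv_block_spec <- function(in_channels, mid_channels,
                            out_channels = 4L * mid_channels,
                            downsample = TRUE) {
  list(in_channels = as.integer(in_channels),
       mid_channels = as.integer(mid_channels),
       out_channels = as.integer(out_channels),
       downsample = isTRUE(downsample))
}

# shortcut builders -------------------------------------------------------

# improved: 3x3 average pool (stride 2, pad 1) -> 1x1 stride-1 conv -> BN.
# every input position contributes to some pooled output.
shortcut_improved <- function(cin, cout, pool_k = 3L) {
  pool_pad <- if (pool_k == 3L) 1L else 0L
  pool <- nn_layer(function(x, training, self)
    ag_avg_pool2d(x, pool_k, 2L, pool_pad), extra = list(kind = "avgpool"))
  nn_sequential(pool, nn_conv2d(cin, cout, 1L, 1L, 0L), nn_batchnorm2d(cout))
}

# original: 1x1 stride-2 conv -> BN. samples only 1 of 4 positions.
shortcut_original <- function(cin, cout) {
  nn_sequential(nn_conv2d(cin, cout, 1L, 2L, 0L), nn_batchnorm2d(cout))
}

#' Downsampling residual bottleneck block
#'
#' The improved variant moves the stride-2 downsampling onto a 3x3 kernel
#' in the main path (1x1 stride-1 for feature extraction first) and
#' replaces the shortcut's strided 1x1 convolution with a 3x3 average
#' pool (stride 2) followed by a 1x1 stride-1 convolution, so no input
#' position is skipped. The original variant downsamples with 1x1
#' stride-2 convolutions on both paths.
#'
#' @param spec a [conv_block_spec()].
#' @param improved use the average-pool variant?
#' @param pool_k pooling window of the improved shortcut (3 default, 2
#'   optional).
#' @returns an internal layer object; apply with `nn_forward`. Its
#'   `shortcut` and `main` children are exposed for inspection.
#' @export
improved_conv_block <- function(spec, improved = TRUE, pool_k = 3L) {
  cin <- spec$in_channels; mid <- spec$mid_channels; cout <- spec$out_channels
  s <- if (spec$downsample) 2L else 1L
  main <- if (improved || !spec$downsample) {
    nn_sequential(
      nn_conv2d(cin, mid, 1L, 1L, 0L), nn_batchnorm2d(mid), nn_relu(),
      nn_conv2d(mid, mid, 3L, s, 1L), nn_batchnorm2d(mid), nn_relu(),
      nn_conv2d(mid, cout, 1L, 1L, 0L), nn_batchnorm2d(cout))
  } else {
    nn_sequential(
      nn_conv2d(cin, mid, 1L, s, 0L), nn_batchnorm2d(mid), nn_relu(),
      nn_conv2d(mid, mid, 3L, 1L, 1L), nn_batchnorm2d(mid), nn_relu(),
      nn_conv2d(mid, cout, 1L, 1L, 0L), nn_batchnorm2d(cout))
  }
  shortcut <- if (!spec$downsample) {
    if (cin == cout) NULL
    else nn_sequential(nn_conv2d(cin, cout, 1L, 1L, 0L), nn_batchnorm2d(cout))
  } else if (improved) shortcut_improved(cin, cout, pool_k)
  else shortcut_original(cin, cout)
  block <- nn_layer(function(x, training, self) {
    if (self$spec$downsample && dim(ag_value(x))[1] %% 2 != 0)
      stop("downsampling block needs an even spatial side")
    m <- nn_forward(self$children$main, x, training)
    sc <- if (is.null(self$children$shortcut)) x
          else nn_forward(self$children$shortcut, x, training)
    ag_relu(ag_add(m, sc))
  }, children = Filter(Negate(is.null),
                       list(main = main, shortcut = shortcut)),
  extra = list(kind = "conv_block", spec = spec, improved = improved))
  block
}

# basic (two 3x3) residual block for the 18/34-layer variants
basic_block <- function(cin, cout, downsample, improved = TRUE, pool_k = 3L) {
  s <- if (downsample) 2L else 1L
  main <- nn_sequential(
    nn_conv2d(cin, cout, 3L, s, 1L), nn_batchnorm2d(cout), nn_relu(),
    nn_conv2d(cout, cout, 3L, 1L, 1L), nn_batchnorm2d(cout))
  shortcut <- if (!downsample && cin == cout) NULL
  else if (downsample && improved) shortcut_improved(cin, cout, pool_k)
  else if (downsample) shortcut_original(cin, cout)
  else nn_sequential(nn_conv2d(cin, cout, 1L, 1L, 0L), nn_batchnorm2d(cout))
  nn_layer(function(x, training, self) {
    m <- nn_forward(self$children$main, x, training)
    sc <- if (is.null(self$children$shortcut)) x
          else nn_forward(self$children$shortcut, x, training)
    ag_relu(ag_add(m, sc))
  }, children = Filter(Negate(is.null), list(main = main, shortcut = shortcut)),
  extra = list(kind = "basic_block"))
}

backbone_layouts <- list(
  resnet18 = list(blocks = c(2, 2, 2, 2), bottleneck = FALSE),
  resnet34 = list(blocks = c(3, 4, 6, 3), bottleneck = FALSE),
  resnet50 = list(blocks = c(3, 4, 6, 3), bottleneck = TRUE),
  resnet101 = list(blocks = c(3, 4, 23, 3), bottleneck = TRUE)
)

#' Build a ResNet-style feature-extraction backbone
#'
#' Standard stage layout (stem 7x7/2 + max pool /2, then four stages, the
#' last three opening with a stride-2 block) giving an output stride of
#' 32. With `improved = TRUE` every downsampling residual block uses the
#' average-pool shortcut of [improved_conv_block()].
#'
#' @param variant one of `"resnet18"`, `"resnet34"`, `"resnet50"`,
#'   `"resnet101"`.
#' @param improved use improved downsampling blocks?
#' @param base_width stem width (64 for the standard networks; smaller
#'   values give proportionally narrower models for desk-scale training).
#' @param in_channels input image channels.
#' @param pool_k improved-shortcut pooling window.
#' @param out_stride 32 (standard four-stage layout) or 16 (drop the last
#'   stage for a finer feature map at small input sizes).
#' @returns layer object; `$out_channels` gives the final feature depth.
#' @export
build_backbone <- function(variant = "resnet50", improved = TRUE,
                           base_width = 64L, in_channels = 3L, pool_k = 3L,
                           out_stride = 32L) {
  lay <- backbone_layouts[[variant]]
  if (is.null(lay)) stop("unknown backbone variant: ", variant)
  if (!out_stride %in% c(8L, 16L, 32L)) stop("out_stride must be 8, 16 or 32")
  n_stages <- c(`8` = 2L, `16` = 3L, `32` = 4L)[[as.character(out_stride)]]
  bw <- as.integer(base_width)
  stem <- nn_sequential(
    nn_conv2d(in_channels, bw, 7L, 2L, 3L), nn_batchnorm2d(bw), nn_relu())
  stages <- list()
  cin <- bw
  for (st in seq_len(n_stages)) {
    width <- bw * 2L^(st - 1L)
    cout <- if (lay$bottleneck) 4L * width else width
    blocks <- list()
    for (b in seq_len(lay$blocks[st])) {
      down <- (st > 1) && (b == 1)
      if (lay$bottleneck) {
        blocks[[b]] <- improved_conv_block(
          conv_block_spec(cin, width, cout, downsample = down),
          improved = improved, pool_k = pool_k)
      } else {
        blocks[[b]] <- basic_block(cin, cout, down, improved, pool_k)
      }
      cin <- cout
    }
    stages[[st]] <- nn_sequential(blocks)
  }
  bb <- nn_layer(function(x, training, self) {
    x <- nn_forward(self$children$stem, x, training)
    x <- ag_max_pool2d(x, 3L, 2L, 1L)
    for (st in self$children$stages$children) x <- nn_forward(st, x, training)
    x
  }, children = list(stem = stem, stages = nn_sequential(stages)),
  extra = list(kind = "backbone", variant = variant, improved = improved))
  bb$out_channels <- cin
  bb
}

#' Count trainable parameters of a model component
#' @param layer a layer/model object.
#' @export
count_params <- function(layer) n_params(layer)

#' Gradient occupancy of a layer
#'
#' Fraction of input positions that receive a nonzero gradient of the
#' summed output: measures how much of the input actually participates in
#' the computation. A 1x1 stride-2 convolution covers 1/4 of positions;
#' an average-pool (stride 2) shortcut covers all of them.
#'
#' @param layer layer object (e.g. a block's `children$shortcut`).
#' @param side input spatial side.
#' @param cin input channels.
#' @param seed RNG seed for the probe input.
#' @returns fraction in `[0, 1]` of input positions with nonzero gradient.
#' @export
gradient_occupancy <- function(layer, side, cin, seed = 1L) {
  set.seed(seed)
  x <- array(stats::runif(side * side * cin, 0.5, 1.5), c(side, side, cin, 1))
  ag_begin(); on.exit(ag_end())
  xn <- ag_param(x)
  out <- nn_forward(layer, xn, training = TRUE)
  # random cotangent: a plain sum has zero gradient through the
  # mean-centering of batch norm and would under-report coverage
  wgt <- array(stats::rnorm(length(out$v)), dim(out$v))
  ag_backward(ag_sum(ag_mul(out, ag_const(wgt))))
  g <- apply(abs(xn$g), c(1, 2), sum)   # collapse channels
  mean(g > 1e-12)
}

#' Two-dimensional sinusoidal positional encoding
#'
#' Fixed encoding with half the channels devoted to each axis; within an
#' axis, sine/cosine pairs at geometrically spaced frequencies
#' (temperature 10000). All values lie in `[-1, 1]`. Token order matches
#' column-major flattening of an `(h, w)` feature map.
#'
#' @param h,w feature-map height and width.
#' @param dim encoding dimension (even; `dim/2` per axis).
#' @param temperature frequency scale.
#' @returns `(h*w) x dim` matrix.
#' @export
positional_encoding <- function(h, w, dim, temperature = 10000) {
  if (dim %% 2 != 0) stop("positional encoding dim must be even")
  half <- dim %/% 2
  if (half %% 2 != 0) stop("dim/2 must also be even (sin/cos pairs per axis)")
  t_idx <- seq_len(h * w) - 1L
  ys <- t_idx %% h; xs <- t_idx %/% h
  npair <- half %/% 2
  freqs <- 1 / temperature^((seq_len(npair) - 1) / npair)
  enc_axis <- function(pos) {
    ang <- outer(pos, freqs)
    out <- matrix(0, length(pos), half)
    out[, seq(1, half, by = 2)] <- sin(ang)
    out[, seq(2, half, by = 2)] <- cos(ang)
    out
  }
  cbind(enc_axis(ys), enc_axis(xs))
}

#' Detector configuration
#'
#' @param num_queries fixed prediction-set size (must exceed the maximum
#'   object count per image).
#' @param hidden_dim transformer width (divisible by `heads`).
#' @param encoder_layers,decoder_layers,heads transformer shape.
#' @param backbone_variant,improved,base_width,pool_k backbone options,
#'   see [build_backbone()].
#' @param image_side input image side, pixels.
#' @param ffn_dim feed-forward width inside transformer layers.
#' @param box_loss `"ciou"` (default) or `"giou"` border-loss family.
#' @param lambda_ciou,lambda_l1 border-loss weights (also used in the
#'   matching cost).
#' @param no_object_weight class weight of the no-object class.
#' @param lr,lr_backbone,weight_decay,grad_clip AdamW settings.
#' @export
#' @param feature_stride backbone output stride (16 suits small inputs,
#'   32 is the classical layout).
#' @param prior_box_size initial box extent the box head is biased
#'   towards (the typical normalized cell size; stabilizes early
#'   matching).
detector_config <- function(num_queries = 25L, hidden_dim = 64L,
                            encoder_layers = 1L, decoder_layers = 3L,
                            heads = 4L, backbone_variant = "resnet18",
                            improved = TRUE, base_width = 16L, pool_k = 3L,
                            image_side = 128L, ffn_dim = 128L,
                            box_loss = c("ciou", "giou"),
                            lambda_ciou = 2, lambda_l1 = 5,
                            no_object_weight = 0.1,
                            feature_stride = 8L, prior_box_size = 0.12,
                            lr = 3e-3, lr_backbone = 3e-3,
                            weight_decay = 1e-4, grad_clip = 5) {
  box_loss <- match.arg(box_loss)
  stopifnot(hidden_dim %% heads == 0)
  as.list(environment())
}

# transformer sublayers ----------------------------------------------------

make_encoder_layer <- function(d, heads, ffn_dim) {
  nn_layer(NULL, children = list(
    mha = nn_mha(d, heads), ln1 = nn_layernorm(d),
    ffn = nn_sequential(nn_linear(d, ffn_dim), nn_relu(), nn_linear(ffn_dim, d)),
    ln2 = nn_layernorm(d)), extra = list(kind = "encoder_layer"))
}

make_decoder_layer <- function(d, heads, ffn_dim) {
  nn_layer(NULL, children = list(
    self_mha = nn_mha(d, heads), ln1 = nn_layernorm(d),
    cross_mha = nn_mha(d, heads), ln2 = nn_layernorm(d),
    ffn = nn_sequential(nn_linear(d, ffn_dim), nn_relu(), nn_linear(ffn_dim, d)),
    ln3 = nn_layernorm(d)), extra = list(kind = "decoder_layer"))
}

#' Build the set-prediction detector
#'
#' @param config a [detector_config()].
#' @param seed seed for weight initialization.
#' @returns model object (environment) with `$config` and sub-modules.
#' @export
build_detector <- function(config = detector_config(), seed = 1L) {
  set.seed(seed)
  d <- config$hidden_dim
  backbone <- build_backbone(config$backbone_variant, config$improved,
                             config$base_width, 3L, config$pool_k,
                             out_stride = config$feature_stride)
  input_proj <- nn_conv2d(backbone$out_channels, d, 1L, 1L, 0L)
  enc <- lapply(seq_len(config$encoder_layers), function(i)
    make_encoder_layer(d, config$heads, config$ffn_dim))
  dec <- lapply(seq_len(config$decoder_layers), function(i)
    make_decoder_layer(d, config$heads, config$ffn_dim))
  query_embed <- ag_param(matrix(stats::rnorm(config$num_queries * d, 0, 0.5),
                                 config$num_queries, d))
  # learnable 2-D anchor points (stored as logits), initialized on a
  # jittered grid covering the image: each query is a spatial probe
  nq <- config$num_queries
  g <- ceiling(sqrt(nq))
  gx <- ((seq_len(nq) - 1) %% g + 0.5) / g
  gy <- ((seq_len(nq) - 1) %/% g + 0.5) / g
  jit <- matrix(stats::runif(2 * nq, -0.2 / g, 0.2 / g), nq, 2)
  anchors <- ag_param(stats::qlogis(pmin(pmax(
    matrix(c(gx, gy), nq, 2) + jit, 0.02), 0.98)))
  class_head <- nn_linear(d, 2L)     # wbc, no-object
  box_head <- nn_sequential(nn_linear(d, d), nn_relu(), nn_linear(d, 4L))
  # bias the initial (w, h) towards the typical cell size so early
  # Hungarian matching is not dominated by oversized boxes
  wh_bias <- stats::qlogis(config$prior_box_size)
  box_head$children[[3]]$params$b$v <- c(0, 0, wh_bias, wh_bias)
  fs <- config$image_side %/% config$feature_stride
  pos <- positional_encoding(fs, fs, d)
  model <- nn_layer(NULL, children = c(
    list(backbone = backbone, input_proj = input_proj,
         class_head = class_head, box_head = box_head,
         enc_norm = nn_layernorm(d), mem_norm = nn_layernorm(d),
         dec_norm = nn_layernorm(d)),
    stats::setNames(enc, paste0("enc", seq_along(enc))),
    stats::setNames(dec, paste0("dec", seq_along(dec)))),
    params = list(query_embed = query_embed, anchors = anchors),
    extra = list(kind = "detr", config = config, pos = pos))
  # token-center coordinates in [0, 1], matching the flattening order
  t_idx <- seq_len(fs * fs) - 1L
  model$token_xy <- cbind(x = ((t_idx %/% fs) + 0.5) / fs,
                          y = ((t_idx %% fs) + 0.5) / fs)
  model$anchor_sigma <- 0.15
  model$config <- config
  model
}

# forward pass on a batch array (H, W, 3, N); returns per-image list of
# nodes (logits Q x 2, boxes Q x 4). With aux = TRUE, logits/boxes are
# lists with one entry per decoder layer (shared prediction heads), the
# last entry being the final output — the auxiliary supervision that
# set-prediction training needs to converge quickly.
detr_forward <- function(model, images, training = FALSE, aux = FALSE) {
  cfg <- model$config
  feat <- nn_forward(model$children$backbone, images, training)
  feat <- nn_forward(model$children$input_proj, feat, training)
  d <- dim(feat$v)
  fh <- d[1]; fw <- d[2]; C <- d[3]; N <- d[4]
  pos <- ag_const(model$pos)
  out <- vector("list", N)
  for (n in seq_len(N)) {
    x <- ag_reshape(ag_cols4(feat, n), c(fh * fw, C))
    # pre-norm blocks (stable without lr warmup); positional encodings
    # enter every attention through queries and keys only
    for (i in seq_len(cfg$encoder_layers)) {
      l <- model$children[[paste0("enc", i)]]
      xn <- nn_forward(l$children$ln1, x, training)
      xp <- ag_add(xn, pos)
      x <- ag_add(x, l$children$mha$attend(xp, xp, xn, training))
      x <- ag_add(x, nn_forward(l$children$ffn,
                                nn_forward(l$children$ln2, x, training),
                                training))
    }
    x <- nn_forward(model$children$enc_norm, x, training)
    # decoder state starts at zero; the learned query embeddings act as
    # per-query positional codes
    qe <- model$params$query_embed
    q <- ag_const(matrix(0, cfg$num_queries, C))
    layer_logits <- list(); layer_boxes <- list()
    # memory values carry the positional code too: with a shallow
    # encoder the attended content average must itself encode "where",
    # or the box head has nothing to regress coordinates from
    xn_mem <- ag_add(nn_forward(model$children$mem_norm, x, training), pos)
    xp_mem <- xn_mem
    # anchor-point spatial prior with layer-wise refinement: each
    # query's 2-D reference point biases cross-attention towards its
    # neighbourhood and anchors the center regression; every decoder
    # layer replaces the reference by its predicted center
    Tn <- nrow(model$token_xy)
    ones1T <- ag_const(matrix(1, 1, Tn))
    onesQ1 <- ag_const(matrix(1, cfg$num_queries, 1))
    tx_row <- ag_const(matrix(model$token_xy[, "x"], 1))
    ty_row <- ag_const(matrix(model$token_xy[, "y"], 1))
    anchor_bias <- function(anchor_logits) {
      axy <- ag_sigmoid(anchor_logits)
      dx <- ag_sub(ag_matmul(ag_cols(axy, 1), ones1T),
                   ag_matmul(onesQ1, tx_row))
      dy <- ag_sub(ag_matmul(ag_cols(axy, 2), ones1T),
                   ag_matmul(onesQ1, ty_row))
      ag_scale(ag_add(ag_square(dx), ag_square(dy)),
               -1 / (2 * model$anchor_sigma^2))
    }
    anchor_logits <- model$params$anchors
    for (i in seq_len(cfg$decoder_layers)) {
      l <- model$children[[paste0("dec", i)]]
      qn <- nn_forward(l$children$ln1, q, training)
      qp <- ag_add(qn, qe)
      q <- ag_add(q, l$children$self_mha$attend(qp, qp, qn, training))
      qn <- nn_forward(l$children$ln2, q, training)
      att_env <- new.env(parent = emptyenv())
      q <- ag_add(q, l$children$cross_mha$attend(ag_add(qn, qe), xp_mem,
                                                 xn_mem, training,
                                                 bias = anchor_bias(anchor_logits),
                                                 att_out = att_env))
      q <- ag_add(q, nn_forward(l$children$ffn,
                                nn_forward(l$children$ln3, q, training),
                                training))
      qh <- nn_forward(model$children$dec_norm, q, training)
      raw <- nn_forward(model$children$box_head, qh, training)
      # soft-argmax readout: the attention distribution's expected token
      # coordinate is a sub-token-precise location estimate; the head
      # regresses a residual around it in logit space
      exp_xy <- ag_matmul(att_env$att, ag_const(unname(model$token_xy)))
      ctr_logits <- ag_add(ag_cols(raw, 1:2), ag_logit(exp_xy))
      if (aux || i == cfg$decoder_layers) {
        ctr <- ag_sigmoid(ctr_logits)
        wh <- ag_sigmoid(ag_cols(raw, 3:4))
        layer_logits[[length(layer_logits) + 1]] <-
          nn_forward(model$children$class_head, qh, training)
        layer_boxes[[length(layer_boxes) + 1]] <- ag_cbind(ctr, wh)
      }
      anchor_logits <- ctr_logits          # refined reference points
    }
    out[[n]] <- if (aux) {
      list(logits = layer_logits[[length(layer_logits)]],
           boxes = layer_boxes[[length(layer_boxes)]],
           aux_logits = layer_logits, aux_boxes = layer_boxes)
    } else {
      list(logits = layer_logits[[1]], boxes = layer_boxes[[1]])
    }
  }
  out
}

# slice batch element n from a (H, W, C, N) node
ag_cols4 <- function(x, n) {
  x <- as_node(x)
  d <- dim(x$v)
  new_node(x$v[, , , n, drop = FALSE], list(x), function(g) {
    gx <- array(0, d); gx[, , , n] <- g; list(gx)
  })
}

# differentiable border loss on matched pairs ------------------------------
# pred: ag node (n x 4, normalized cxcywh); target: plain matrix (n x 4).
# Returns scalar node: sum over pairs of lambda_iou * L_iou-family +
# lambda_l1 * L1. The CIOU trade-off weight a is treated as a constant.
ag_box_loss <- function(pred, target, type = "ciou",
                        lambda_ciou = 2, lambda_l1 = 5) {
  tg <- ag_const(target)
  px <- ag_cols(pred, 1); py <- ag_cols(pred, 2)
  pw <- ag_cols(pred, 3); ph <- ag_cols(pred, 4)
  tx <- target[, 1, drop = FALSE]; ty <- target[, 2, drop = FALSE]
  tw <- target[, 3, drop = FALSE]; th <- target[, 4, drop = FALSE]
  px0 <- ag_sub(px, ag_scale(pw, 0.5)); px1 <- ag_add(px, ag_scale(pw, 0.5))
  py0 <- ag_sub(py, ag_scale(ph, 0.5)); py1 <- ag_add(py, ag_scale(ph, 0.5))
  tx0 <- tx - tw / 2; tx1 <- tx + tw / 2; ty0 <- ty - th / 2; ty1 <- ty + th / 2
  iw <- ag_relu(ag_sub(ag_minimum(px1, ag_const(tx1)), ag_maximum(px0, ag_const(tx0))))
  ih <- ag_relu(ag_sub(ag_minimum(py1, ag_const(ty1)), ag_maximum(py0, ag_const(ty0))))
  inter <- ag_mul(iw, ih)
  union <- ag_sub(ag_add(ag_mul(pw, ph), ag_const(tw * th)), inter)
  iou_n <- ag_div(inter, union)
  hx0 <- ag_minimum(px0, ag_const(tx0)); hx1 <- ag_maximum(px1, ag_const(tx1))
  hy0 <- ag_minimum(py0, ag_const(ty0)); hy1 <- ag_maximum(py1, ag_const(ty1))
  hw <- ag_sub(hx1, hx0); hh <- ag_sub(hy1, hy0)
  if (type == "ciou") {
    d2 <- ag_add(ag_square(ag_sub(px, ag_const(tx))),
                 ag_square(ag_sub(py, ag_const(ty))))
    c2 <- ag_add(ag_square(hw), ag_square(hh))
    v <- ag_scale(ag_square(ag_sub(ag_const(atan(tw / th)),
                                   ag_atan(ag_div(pw, ph)))), 4 / pi^2)
    alpha <- v$v / ((1 - iou_n$v) + v$v)     # constant within the step
    alpha[v$v == 0] <- 0
    per_pair <- ag_add(ag_add(ag_sub(ag_shift(ag_neg(iou_n), 1), ag_neg(ag_div(d2, c2))),
                              ag_mul(ag_const(alpha), v)),
                       ag_const(matrix(0, nrow(target), 1)))
  } else {
    hull <- ag_mul(hw, hh)
    giou_n <- ag_sub(iou_n, ag_div(ag_sub(hull, union), hull))
    per_pair <- ag_shift(ag_neg(giou_n), 1)
  }
  l1 <- ag_sum(ag_abs(ag_sub(pred, tg)))
  ag_add(ag_scale(ag_sum(per_pair), lambda_ciou), ag_scale(l1, lambda_l1))
}

#' One training step: match, compute loss, backpropagate
#'
#' Hungarian-matches each image's queries to its ground-truth boxes with a
#' cost combining class probability and border loss, then minimizes a
#' weighted cross-entropy (no-object down-weighted) plus the combined
#' CIOU/GIOU + L1 border loss over matched pairs, normalized by the
#' target count.
#'
#' @param model detector from [build_detector()].
#' @param images `(H, W, 3, N)` array in `[0, 1]`.
#' @param targets list of length N; each a matrix `n_i x 4` of normalized
#'   center-format boxes (may have zero rows).
#' @param opt optional `adamw` optimizer; when given, performs the update.
#' @returns list `loss`, `class_loss`, `box_loss` (per-target mean of the
#'   weighted combined border loss), `box_iou_loss` (per-target mean of
#'   the unweighted CIOU/GIOU component, the convergence monitor),
#'   `n_targets`.
#' @export
training_step <- function(model, images, targets, opt = NULL) {
  cfg <- model$config
  ag_begin(); on.exit(ag_end())
  preds <- detr_forward(model, images - 0.5, training = TRUE, aux = TRUE)
  n_tot <- max(1L, sum(vapply(targets, nrow, 0L)))
  box_terms <- NULL; cls_terms <- list()
  iou_component <- 0   # unweighted CIOU/GIOU family loss, final layer only
  n_layers <- length(preds[[1]]$aux_logits)
  for (n in seq_along(preds)) {
    tgt <- targets[[n]]
    for (lay in seq_len(n_layers)) {
      logits <- preds[[n]]$aux_logits[[lay]]
      boxes <- preds[[n]]$aux_boxes[[lay]]
      labels <- rep(2L, cfg$num_queries)        # all no-object by default
      if (!is.null(tgt) && nrow(tgt) > 0) {
        cost <- matching_cost(logits$v, boxes$v, tgt, cfg)
        assign_idx <- hungarian_match(cost)$assignment
        labels[assign_idx] <- 1L
        bl <- ag_box_loss(ag_rows(boxes, assign_idx), tgt, cfg$box_loss,
                          cfg$lambda_ciou, cfg$lambda_l1)
        box_terms <- if (is.null(box_terms)) bl else ag_add(box_terms, bl)
        if (lay == n_layers) for (i in seq_len(nrow(tgt))) {
          tb <- bbox(tgt[i, 1], tgt[i, 2], max(tgt[i, 3], 1e-6),
                     max(tgt[i, 4], 1e-6))
          pb <- boxes$v[assign_idx[i], ]
          pb <- bbox(pb[1], pb[2], max(pb[3], 1e-6), max(pb[4], 1e-6))
          iou_component <- iou_component +
            if (cfg$box_loss == "ciou") ciou_loss(tb, pb) else 1 - giou(tb, pb)
        }
      }
      cls_terms[[length(cls_terms) + 1]] <-
        ag_cross_entropy(logits, labels, c(1, cfg$no_object_weight))
    }
  }
  cls_loss <- cls_terms[[1]]
  if (length(cls_terms) > 1)
    for (i in 2:length(cls_terms)) cls_loss <- ag_add(cls_loss, cls_terms[[i]])
  cls_loss <- ag_scale(cls_loss, 1 / length(cls_terms))
  loss <- if (is.null(box_terms)) cls_loss
          else ag_add(cls_loss, ag_scale(box_terms, 1 / (n_tot * n_layers)))
  if (!is.null(opt)) {
    zero_grads(opt$params)
    ag_backward(loss)
    clip_grad_norm(opt$params, model$config$grad_clip)
    adamw_step(opt)
  } else ag_backward(loss)
  list(loss = as.numeric(loss$v), class_loss = as.numeric(cls_loss$v),
       box_loss = if (is.null(box_terms)) 0
                  else as.numeric(box_terms$v) / (n_tot * n_layers),
       box_iou_loss = iou_component / n_tot,
       n_targets = n_tot)
}

# matching cost matrix (targets x queries): -p(wbc) + border loss
matching_cost <- function(logits, boxes, tgt, cfg) {
  z <- logits - apply(logits, 1, max)
  p <- exp(z) / rowSums(exp(z))
  nq <- nrow(boxes); nt <- nrow(tgt)
  cost <- matrix(0, nt, nq)
  for (i in seq_len(nt)) {
    tb <- bbox(tgt[i, 1], tgt[i, 2], max(tgt[i, 3], 1e-6), max(tgt[i, 4], 1e-6))
    for (q in seq_len(nq)) {
      pb <- bbox(boxes[q, 1], boxes[q, 2], max(boxes[q, 3], 1e-6),
                 max(boxes[q, 4], 1e-6))
      bl <- if (cfg$box_loss == "ciou") ciou_loss(tb, pb) else 1 - giou(tb, pb)
      cost[i, q] <- -p[q, 1] + cfg$lambda_ciou * bl +
        cfg$lambda_l1 * sum(abs(unclass(tb) - unclass(pb)))
    }
  }
  cost
}

#' Run the detector on one image
#'
#' @param image `(H, W, 3)` array in `[0, 1]` (or `(H, W, 3, 1)`).
#' @param model detector.
#' @returns data.frame with one row per query: `score` (wbc probability),
#'   `cx`, `cy`, `w`, `h` (normalized center format).
#' @export
forward_detect <- function(image, model) {
  if (length(dim(image)) == 3) dim(image) <- c(dim(image), 1)
  if (dim(image)[1] != model$config$image_side)
    stop("image side does not match the configured detector input size")
  res <- ag_no_grad(detr_forward(model, image - 0.5, training = FALSE))[[1]]
  z <- res$logits$v - apply(res$logits$v, 1, max)
  p <- exp(z) / rowSums(exp(z))
  b <- res$boxes$v
  data.frame(score = p[, 1], cx = b[, 1], cy = b[, 2], w = b[, 3], h = b[, 4])
}

#' Train the detector on an in-memory dataset
#'
#' @param images list of `(H, W, 3)` arrays in `[0, 1]`.
#' @param targets list of normalized `n x 4` box matrices (cx, cy, w, h).
#' @param config a [detector_config()].
#' @param epochs training epochs.
#' @param batch_size images per optimization step.
#' @param seed governs initialization and shuffling.
#' @param verbose print per-epoch losses?
#' @returns list `model`, `history` (per-epoch data.frame), `step_box_loss`
#'   (per-step border-loss trace, for convergence comparisons).
#' @export
train_detector <- function(images, targets, config = detector_config(),
                           epochs = 30L, batch_size = 8L, seed = 1L,
                           verbose = FALSE) {
  model <- build_detector(config, seed = seed)
  params <- collect_params(model)
  bb_names <- grepl("^backbone", names(params))
  opt_main <- adamw(params[!bb_names], lr = config$lr,
                    weight_decay = config$weight_decay)
  opt_bb <- adamw(params[bb_names], lr = config$lr_backbone,
                  weight_decay = config$weight_decay)
  opt <- list(params = params, main = opt_main, bb = opt_bb)
  set.seed(seed + 1L)
  n <- length(images)
  side <- config$image_side
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     class_loss = numeric(), box_loss = numeric(),
                     box_iou_loss = numeric())
  step_box <- numeric(0)
  for (ep in seq_len(epochs)) {
    # cosine decay to 5% of the base rate: late epochs refine boxes
    fac <- 0.05 + 0.95 * (1 + cos(pi * (ep - 1) / max(1, epochs - 1))) / 2
    opt$main$lr <- config$lr * fac
    opt$bb$lr <- config$lr_backbone * fac
    ord <- sample.int(n)
    ep_loss <- ep_cls <- ep_box <- ep_iou <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      batch <- array(0, c(side, side, 3, length(idx)))
      for (j in seq_along(idx)) batch[, , , j] <- images[[idx[j]]]
      st <- training_step_opt(model, batch, targets[idx], opt)
      ep_loss <- ep_loss + st$loss; ep_cls <- ep_cls + st$class_loss
      ep_box <- ep_box + st$box_loss; ep_iou <- ep_iou + st$box_iou_loss
      nb <- nb + 1
      step_box <- c(step_box, st$box_iou_loss)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / nb,
                                   class_loss = ep_cls / nb,
                                   box_loss = ep_box / nb,
                                   box_iou_loss = ep_iou / nb))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  class %.4f  box %.4f  iou %.4f",
                      ep, ep_loss / nb, ep_cls / nb, ep_box / nb,
                      ep_iou / nb))
  }
  list(model = model, history = hist, step_box_loss = step_box)
}

# training_step with the split backbone/head optimizer
training_step_opt <- function(model, images, targets, opt) {
  st <- training_step(model, images, targets, opt = NULL)
  clip_grad_norm(opt$params, model$config$grad_clip)
  adamw_step(opt$main); adamw_step(opt$bb)
  zero_grads(opt$params)
  st
}

#' Mean average precision at a fixed IOU threshold
#'
#' Single-class AP by all-point interpolation of the precision-recall
#' curve: detections are ranked by confidence across images, greedily
#' matched (per image) to unmatched ground-truth boxes at
#' `IOU >= iou_threshold`, and AP is the area under the interpolated
#' precision envelope.
#'
#' @param predictions data.frame with `image_id`, `score`, `cx`, `cy`,
#'   `w`, `h` (normalized center format).
#' @param ground_truth data.frame with `image_id`, `cx`, `cy`, `w`, `h`.
#' @param iou_threshold match threshold (default 0.5).
#' @returns AP in `[0, 1]` (single foreground class, so mAP = AP).
#' @export
evaluate_map <- function(predictions, ground_truth, iou_threshold = 0.5) {
  n_gt <- nrow(ground_truth)
  if (is.null(predictions) || nrow(predictions) == 0)
    return(0)
  if (n_gt == 0) {
    warning("no ground-truth boxes; AP defined as 0")
    return(0)
  }
  ord <- order(-predictions$score)
  preds <- predictions[ord, , drop = FALSE]
  matched <- rep(FALSE, n_gt)
  tp <- numeric(nrow(preds))
  for (i in seq_len(nrow(preds))) {
    cand <- which(ground_truth$image_id == preds$image_id[i] & !matched)
    if (length(cand) == 0) next
    ious <- vapply(cand, function(j)
      iou(c(cx = preds$cx[i], cy = preds$cy[i],
            w = max(preds$w[i], 1e-9), h = max(preds$h[i], 1e-9)),
          c(cx = ground_truth$cx[j], cy = ground_truth$cy[j],
            w = ground_truth$w[j], h = ground_truth$h[j])), 0)
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[i] <- 1
      matched[cand[best]] <- TRUE
    }
  }
  cum_tp <- cumsum(tp); cum_fp <- cumsum(1 - tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  # all-point interpolation: precision envelope integrated over recall
  mrec <- c(0, recall, 1)
  mpre <- c(0, precision, 0)
  for (i in (length(mpre) - 1):1) mpre[i] <- max(mpre[i], mpre[i + 1])
  idx <- which(mrec[-1] != mrec[-length(mrec)])
  sum((mrec[idx + 1] - mrec[idx]) * mpre[idx + 1])
}
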