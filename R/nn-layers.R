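# Neural-network layer constructors over the autograd engine, plus the
# AdamW optimizer. A layer is an environment with $params (named list of
# ag_param nodes), optional $children (sub-layers), and $fwd(x, training).

nn_layer <- function(fwd, params = list(), children = list(), extra = list()) {
  e <- new.env(parent = emptyenv())
  e$params <- params; e$children <- children
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  e$fwd <- fwd
  class(e) <- "nn_layer"
  e
}

nn_forward <- function(layer, x, training = FALSE) layer$fwd(x, training, layer)

nn_conv2d <- function(cin, cout, k, stride = 1L, pad = 0L, bias = TRUE,
                      init_sd = sqrt(2 / (k * k * cin))) {
  W <- ag_param(matrix(stats::rnorm(k * k * cin * cout, 0, init_sd),
                       k * k * cin, cout))
  b <- ag_param(numeric(cout))
  nn_layer(function(x, training, self)
    ag_conv2d(x, self$params$W, self$params$b, k, k, stride, pad),
    params = list(W = W, b = b),
    extra = list(kind = "conv2d", cin = cin, cout = cout, k = k,
                 stride = stride, pad = pad))
}

nn_conv_transpose2d <- function(cin, cout, k = 4L, stride = 2L, pad = 1L,
                                init_sd = sqrt(2 / (k * k * cin))) {
  W <- ag_param(matrix(stats::rnorm(k * k * cout * cin, 0, init_sd),
                       k * k * cout, cin))
  b <- ag_param(numeric(cout))
  nn_layer(function(x, training, self)
    ag_conv_transpose2d(x, self$params$W, self$params$b, k, k, stride, pad),
    params = list(W = W, b = b),
    extra = list(kind = "conv_transpose2d", cin = cin, cout = cout, k = k,
                 stride = stride, pad = pad))
}

nn_batchnorm2d <- function(c) {
  gamma <- ag_param(rep(1, c)); beta <- ag_param(numeric(c))
  l <- nn_layer(function(x, training, self)
    ag_batchnorm2d(x, self$params$gamma, self$params$beta, self, training),
    params = list(gamma = gamma, beta = beta),
    extra = list(kind = "batchnorm2d",
                 running_mean = numeric(c), running_var = rep(1, c)))
  l
}

nn_linear <- function(din, dout, init_sd = sqrt(2 / din)) {
  W <- ag_param(matrix(stats::rnorm(din * dout, 0, init_sd), din, dout))
  b <- ag_param(numeric(dout))
  nn_layer(function(x, training, self)
    ag_linear(x, self$params$W, self$params$b),
    params = list(W = W, b = b),
    extra = list(kind = "linear", din = din, dout = dout))
}

nn_layernorm <- function(d) {
  gamma <- ag_param(rep(1, d)); beta <- ag_param(numeric(d))
  nn_layer(function(x, training, self)
    ag_layernorm(x, self$params$gamma, self$params$beta),
    params = list(gamma = gamma, beta = beta),
    extra = list(kind = "layernorm"))
}

nn_relu <- function() nn_layer(function(x, training, self) ag_relu(x),
                               extra = list(kind = "relu"))
nn_leaky_relu <- function(slope = 0.2)
  nn_layer(function(x, training, self) ag_leaky_relu(x, slope),
           extra = list(kind = "leaky_relu"))

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) && !inherits(layers[[1]], "nn_layer"))
    layers <- layers[[1]]
  nn_layer(function(x, training, self) {
    for (l in self$children) x <- nn_forward(l, x, training)
    x
  }, children = layers, extra = list(kind = "sequential"))
}

# Multi-head attention over token matrices (T x D). q, k, v are matrices;
# heads split along the feature dimension.
nn_mha <- function(d, heads) {
  stopifnot(d %% heads == 0)
  mk <- function() nn_linear(d, d, init_sd = sqrt(1 / d))
  l <- nn_layer(NULL, children = list(wq = mk(), wk = mk(), wv = mk(), wo = mk()),
                extra = list(kind = "mha", d = d, heads = heads, dh = d %/% heads))
  # bias: optional (rows(q) x rows(k)) additive attention-logit bias,
  # shared across heads (used for anchor-point spatial priors).
  # att_out: optional environment; if given, receives $att, the
  # head-averaged attention matrix (for soft-argmax readouts).
  l$attend <- function(q_in, k_in, v_in, training = FALSE, bias = NULL,
                       att_out = NULL) {
    q <- nn_forward(l$children$wq, q_in, training)
    k <- nn_forward(l$children$wk, k_in, training)
    v <- nn_forward(l$children$wv, v_in, training)
    dh <- l$dh
    outs <- vector("list", l$heads)
    att_sum <- NULL
    for (h in seq_len(l$heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      qh <- ag_cols(q, idx); kh <- ag_cols(k, idx); vh <- ag_cols(v, idx)
      logits <- ag_scale(ag_matmul(qh, ag_transpose(kh)), 1 / sqrt(dh))
      if (!is.null(bias)) logits <- ag_add(logits, bias)
      att <- ag_softmax_rows(logits)
      if (!is.null(att_out))
        att_sum <- if (is.null(att_sum)) att else ag_add(att_sum, att)
      outs[[h]] <- ag_matmul(att, vh)
    }
    if (!is.null(att_out)) att_out$att <- ag_scale(att_sum, 1 / l$heads)
    nn_forward(l$children$wo, do.call(ag_cbind, outs), training)
  }
  l
}

ag_transpose <- function(a) {
  a <- as_node(a)
  new_node(t(a$v), list(a), function(g) list(t(g)))
}

# recursive parameter collection (named, depth-first)
collect_params <- function(layer, prefix = "") {
  out <- list()
  for (nm in names(layer$params))
    out[[paste0(prefix, nm)]] <- layer$params[[nm]]
  ch <- layer$children
  nms <- names(ch) %||% as.character(seq_along(ch))
  for (i in seq_along(ch))
    out <- c(out, collect_params(ch[[i]],
                                 paste0(prefix, nms[i] %||% i, ".")))
  out
}

n_params <- function(layer) sum(vapply(collect_params(layer),
                                       function(p) length(p$v), 0))

zero_grads <- function(params) { for (p in params) p$g <- NULL; invisible(NULL) }

clip_grad_norm <- function(params, max_norm) {
  tot <- 0
  for (p in params) if (!is.null(p$g)) tot <- tot + sum(p$g^2)
  tot <- sqrt(tot)
  if (tot > max_norm && tot > 0) {
    sc <- max_norm / tot
    for (p in params) if (!is.null(p$g)) p$g <- p$g * sc
  }
  tot
}

## ---- AdamW --------------------------------------------------------------

adamw <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                  weight_decay = 1e-4) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$wd <- weight_decay; opt$t <- 0L
  opt$m <- lapply(params, function(p) p$v * 0)
  opt$s <- lapply(params, function(p) p$v * 0)
  opt
}

adamw_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t; bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$g)) next
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * p$g
    opt$s[[i]] <- opt$beta2 * opt$s[[i]] + (1 - opt$beta2) * p$g^2
    mhat <- opt$m[[i]] / bc1; shat <- opt$s[[i]] / bc2
    p$v <- p$v - opt$lr * (mhat / (sqrt(shat) + opt$eps) + opt$wd * p$v)
  }
  invisible(NULL)
}
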