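# A compact tape-based reverse-mode automatic-differentiation engine.
# Values are R arrays/matrices; nodes are environments recorded on a
# global tape in creation order; backward() walks the tape in reverse.
# Internal: the detector and GAN modules are built on these primitives.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$recording <- FALSE

ag_begin <- function() { .ag$tape <- vector("list", 0L); .ag$recording <- TRUE }
ag_end <- function() { .ag$tape <- NULL; .ag$recording <- FALSE }

ag_no_grad <- function(expr) {
  old_rec <- .ag$recording; old_tape <- .ag$tape
  .ag$recording <- FALSE
  on.exit({ .ag$recording <- old_rec; .ag$tape <- old_tape })
  force(expr)
}

ag_is <- function(x) inherits(x, "ag_node")

new_node <- function(v, parents = list(), bw = NULL, leaf = FALSE) {
  n <- new.env(parent = emptyenv())
  n$v <- v; n$g <- NULL; n$parents <- parents; n$bw <- bw; n$leaf <- leaf
  class(n) <- "ag_node"
  if (.ag$recording && !leaf) .ag$tape[[length(.ag$tape) + 1L]] <- n
  n
}

# leaf holding a constant (no gradient tracked)
ag_const <- function(v) new_node(v, leaf = TRUE)

# trainable leaf; reused across steps, gradient accumulates in $g
ag_param <- function(v) { n <- new_node(v, leaf = TRUE); n$trainable <- TRUE; n }

ag_value <- function(x) if (ag_is(x)) x$v else x
as_node <- function(x) if (ag_is(x)) x else ag_const(x)

accumulate <- function(node, g) {
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
  invisible(NULL)
}

# Reverse pass from a scalar (or given seed gradient).
ag_backward <- function(loss, seed = 1) {
  if (!.ag$recording) stop("no active tape: call ag_begin() before the forward pass")
  loss$g <- seed
  tape <- .ag$tape
  for (i in rev(seq_along(tape))) {
    n <- tape[[i]]
    if (is.null(n$g) || is.null(n$bw)) next
    gs <- n$bw(n$g)
    for (j in seq_along(gs))
      if (!is.null(gs[[j]]) && !isTRUE(n$parents[[j]]$leaf && is.null(n$parents[[j]]$trainable)))
        accumulate(n$parents[[j]], gs[[j]])
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- elementwise ops ----------------------------------------------------

ag_ew2 <- function(a, b, f, dfa, dfb) {
  a <- as_node(a); b <- as_node(b)
  v <- f(a$v, b$v)
  new_node(v, list(a, b), function(g) list(dfa(g, a$v, b$v, v), dfb(g, a$v, b$v, v)))
}

ag_add <- function(a, b) ag_ew2(a, b, `+`,
  function(g, av, bv, v) g, function(g, av, bv, v) g)
ag_sub <- function(a, b) ag_ew2(a, b, `-`,
  function(g, av, bv, v) g, function(g, av, bv, v) -g)
ag_mul <- function(a, b) ag_ew2(a, b, `*`,
  function(g, av, bv, v) g * bv, function(g, av, bv, v) g * av)
ag_div <- function(a, b) ag_ew2(a, b, `/`,
  function(g, av, bv, v) g / bv, function(g, av, bv, v) -g * av / bv^2)
ag_minimum <- function(a, b) ag_ew2(a, b, pmin,
  function(g, av, bv, v) g * (av <= bv), function(g, av, bv, v) g * (av > bv))
ag_maximum <- function(a, b) ag_ew2(a, b, pmax,
  function(g, av, bv, v) g * (av >= bv), function(g, av, bv, v) g * (av < bv))

ag_ew1 <- function(a, f, df) {
  a <- as_node(a)
  v <- f(a$v)
  new_node(v, list(a), function(g) list(df(g, a$v, v)))
}

ag_scale <- function(a, s) ag_ew1(a, function(x) x * s, function(g, x, v) g * s)
ag_shift <- function(a, s) ag_ew1(a, function(x) x + s, function(g, x, v) g)
ag_neg <- function(a) ag_scale(a, -1)
ag_square <- function(a) ag_ew1(a, function(x) x^2, function(g, x, v) 2 * g * x)
ag_sqrt <- function(a) ag_ew1(a, sqrt, function(g, x, v) g / (2 * pmax(v, 1e-12)))
ag_abs <- function(a) ag_ew1(a, abs, function(g, x, v) g * sign(x))
ag_atan <- function(a) ag_ew1(a, atan, function(g, x, v) g / (1 + x^2))
ag_logit <- function(a, eps = 1e-6) ag_ew1(
  a, function(x) stats::qlogis(pmin(pmax(x, eps), 1 - eps)),
  function(g, x, v) { xc <- pmin(pmax(x, eps), 1 - eps); g / (xc * (1 - xc)) })
ag_relu <- function(a) ag_ew1(a, function(x) pmax(x, 0), function(g, x, v) g * (x > 0))
ag_leaky_relu <- function(a, slope = 0.2)
  ag_ew1(a, function(x) pmax(x, 0) + slope * pmin(x, 0),
         function(g, x, v) g * ifelse(x > 0, 1, slope))
ag_tanh <- function(a) ag_ew1(a, tanh, function(g, x, v) g * (1 - v^2))
ag_sigmoid <- function(a) ag_ew1(a, stats::plogis, function(g, x, v) g * v * (1 - v))

ag_sum <- function(a) {
  a <- as_node(a)
  new_node(sum(a$v), list(a), function(g) list(array(as.numeric(g), dim(a$v) %||% length(a$v))))
}
ag_mean <- function(a) ag_scale(ag_sum(a), 1 / length(ag_value(a)))

## ---- shape ops ----------------------------------------------------------

ag_reshape <- function(a, dims) {
  a <- as_node(a)
  v <- a$v; dim(v) <- dims
  old <- dim(a$v) %||% length(a$v)
  new_node(v, list(a), function(g) { dim(g) <- old; list(g) })
}

ag_aperm <- function(a, perm) {
  a <- as_node(a)
  new_node(aperm(a$v, perm), list(a),
           function(g) list(aperm(g, order(perm))))
}

# row/column gather with scatter backward (x is a matrix)
ag_rows <- function(a, idx) {
  a <- as_node(a)
  new_node(a$v[idx, , drop = FALSE], list(a), function(g) {
    gx <- array(0, dim(a$v))
    for (k in seq_along(idx)) gx[idx[k], ] <- gx[idx[k], ] + g[k, ]
    list(gx)
  })
}

ag_cols <- function(a, idx) {
  a <- as_node(a)
  new_node(a$v[, idx, drop = FALSE], list(a), function(g) {
    gx <- array(0, dim(a$v))
    for (k in seq_along(idx)) gx[, idx[k]] <- gx[, idx[k]] + g[, k]
    list(gx)
  })
}

ag_rbind <- function(...) {
  nodes <- lapply(list(...), as_node)
  rows <- vapply(nodes, function(n) nrow(n$v), 0L)
  ends <- cumsum(rows); starts <- ends - rows + 1L
  new_node(do.call(rbind, lapply(nodes, `[[`, "v")), nodes, function(g)
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE]))
}

ag_cbind <- function(...) {
  nodes <- lapply(list(...), as_node)
  cols <- vapply(nodes, function(n) ncol(n$v), 0L)
  ends <- cumsum(cols); starts <- ends - cols + 1L
  new_node(do.call(cbind, lapply(nodes, `[[`, "v")), nodes, function(g)
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE]))
}

## ---- matrix ops ---------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_node(a$v %*% b$v, list(a, b), function(g)
    list(g %*% t(b$v), t(a$v) %*% g))
}

# x (T x Din) %*% W (Din x Dout) + bias (length Dout, broadcast over rows)
ag_linear <- function(x, W, b = NULL) {
  x <- as_node(x); W <- as_node(W)
  v <- x$v %*% W$v
  if (!is.null(b)) {
    b <- as_node(b)
    v <- sweep(v, 2, as.numeric(b$v), `+`)
    new_node(v, list(x, W, b), function(g)
      list(g %*% t(W$v), t(x$v) %*% g, colSums(g)))
  } else {
    new_node(v, list(x, W), function(g)
      list(g %*% t(W$v), t(x$v) %*% g))
  }
}

# softmax over rows of a matrix
ag_softmax_rows <- function(a) {
  a <- as_node(a)
  z <- a$v - apply(a$v, 1, max)
  e <- exp(z); s <- e / rowSums(e)
  new_node(s, list(a), function(g) list((g - rowSums(g * s)) * s))
}

# layer norm over rows; gamma/beta length ncol
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  mu <- rowMeans(x$v)
  xc <- x$v - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  v <- sweep(xhat * matrix(as.numeric(gamma$v), nrow(x$v), ncol(x$v), byrow = TRUE),
             2, as.numeric(beta$v), `+`)
  D <- ncol(x$v)
  new_node(v, list(x, gamma, beta), function(g) {
    gmat <- matrix(as.numeric(gamma$v), nrow(g), ncol(g), byrow = TRUE)
    gxh <- g * gmat
    gx <- istd * (gxh - rowMeans(gxh) - xhat * rowMeans(gxh * xhat))
    list(gx, colSums(g * xhat), colSums(g))
  })
}

# weighted cross entropy from logits (rows = samples); targets 1-based
ag_cross_entropy <- function(logits, targets, class_weights = NULL) {
  logits <- as_node(logits)
  z <- logits$v - apply(logits$v, 1, max)
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  n <- nrow(z); k <- ncol(z)
  w <- if (is.null(class_weights)) rep(1, k) else class_weights
  wi <- w[targets]
  v <- -sum(wi * logp[cbind(seq_len(n), targets)]) / sum(wi)
  p <- exp(logp)
  new_node(v, list(logits), function(g) {
    onehot <- matrix(0, n, k); onehot[cbind(seq_len(n), targets)] <- 1
    list(as.numeric(g) * (p - onehot) * wi / sum(wi))
  })
}

## ---- conv / pool ops (Rcpp-backed) --------------------------------------

# x: (H, W, Cin, N); W matrix (kh*kw*Cin x Cout); b length Cout
ag_conv2d <- function(x, W, b, kh, kw, stride = 1L, pad = 0L) {
  x <- as_node(x); W <- as_node(W); b <- as_node(b)
  d <- dim(x$v)
  H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  OH <- (H + 2 * pad - kh) %/% stride + 1
  OW <- (Wd + 2 * pad - kw) %/% stride + 1
  cols <- cpp_im2col(x$v, H, Wd, C, N, kh, kw, stride, pad)
  out_m <- crossprod(W$v, cols) + as.numeric(b$v)   # (Cout x OH*OW*N), bias recycles rows
  Cout <- ncol(W$v)
  out <- aperm(array(out_m, c(Cout, OH, OW, N)), c(2, 3, 1, 4))
  new_node(out, list(x, W, b), function(g) {
    gm <- matrix(aperm(g, c(3, 1, 2, 4)), nrow = Cout)
    gW <- cols %*% t(gm)
    gb <- rowSums(gm)
    gx <- cpp_col2im(W$v %*% gm, H, Wd, C, N, kh, kw, stride, pad)
    list(gx, gW, gb)
  })
}

# transposed conv: x (Hin, Win, Cin, N); W matrix (kh*kw*Cout x Cin); b Cout
ag_conv_transpose2d <- function(x, W, b, kh, kw, stride = 2L, pad = 1L) {
  x <- as_node(x); W <- as_node(W); b <- as_node(b)
  d <- dim(x$v)
  Hin <- d[1]; Win <- d[2]; Cin <- d[3]; N <- d[4]
  Hout <- (Hin - 1) * stride + kh - 2 * pad
  Wout <- (Win - 1) * stride + kw - 2 * pad
  Cout <- nrow(W$v) %/% (kh * kw)
  xm <- matrix(aperm(x$v, c(3, 1, 2, 4)), nrow = Cin)
  out <- cpp_col2im(W$v %*% xm, Hout, Wout, Cout, N, kh, kw, stride, pad)
  out <- out + rep(rep(as.numeric(b$v), each = Hout * Wout), times = N)
  dim(out) <- c(Hout, Wout, Cout, N)
  new_node(out, list(x, W, b), function(g) {
    gcols <- cpp_im2col(g, Hout, Wout, Cout, N, kh, kw, stride, pad)
    gx_m <- t(W$v) %*% gcols
    gx <- aperm(array(gx_m, c(Cin, Hin, Win, N)), c(2, 3, 1, 4))
    gW <- gcols %*% t(xm)
    gb <- colSums(matrix(aperm(g, c(1, 2, 4, 3)), ncol = Cout))
    list(gx, gW, gb)
  })
}

ag_avg_pool2d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  x <- as_node(x)
  d <- dim(x$v)
  out <- cpp_avgpool_fwd(x$v, d[1], d[2], d[3], d[4], k, stride, pad)
  new_node(out, list(x), function(g)
    list(cpp_avgpool_bwd(g, d[1], d[2], d[3], d[4], k, stride, pad)))
}

ag_max_pool2d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  x <- as_node(x)
  d <- dim(x$v)
  r <- cpp_maxpool_fwd(x$v, d[1], d[2], d[3], d[4], k, stride, pad)
  new_node(r$out, list(x), function(g)
    list(cpp_maxpool_bwd(g, r$argmax, d[1], d[2], d[3], d[4])))
}

# batch norm over (H, W, N) per channel; layer carries running stats
ag_batchnorm2d <- function(x, gamma, beta, layer, training = TRUE, eps = 1e-5,
                           momentum = 0.1) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$v); C <- d[3]
  xp <- aperm(x$v, c(1, 2, 4, 3))
  xm <- matrix(xp, ncol = C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2)
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var + momentum * va
  } else {
    mu <- layer$running_mean; va <- layer$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
  ym <- sweep(sweep(xhat, 2, as.numeric(gamma$v), `*`), 2, as.numeric(beta$v), `+`)
  out <- aperm(array(ym, dim(xp)), c(1, 2, 4, 3))
  m <- nrow(xm)
  new_node(out, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
    gxh <- sweep(gm, 2, as.numeric(gamma$v), `*`)
    if (training) {
      gx_m <- sweep(gxh - matrix(colMeans(gxh), m, C, byrow = TRUE) -
                      sweep(xhat, 2, colMeans(gxh * xhat), `*`),
                    2, istd, `*`)
    } else {
      gx_m <- sweep(gxh, 2, istd, `*`)
    }
    gx <- aperm(array(gx_m, dim(xp)), c(1, 2, 4, 3))
    list(gx, colSums(gm * xhat), colSums(gm))
  })
}
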