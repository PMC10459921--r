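# Independent oracles, deliberately written against corner-form geometry
# (not the package's center-form code paths).

# step-by-step geometric computation from corner boxes (x0, y0, x1, y1)
oracle_geom <- function(a, b) {
  area <- function(z) (z[3] - z[1]) * (z[4] - z[2])
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- if (iw > 0 && ih > 0) iw * ih else 0
  union <- area(a) + area(b) - inter
  hull <- c(min(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), max(a[4], b[4]))
  iou <- inter / union
  giou <- iou - (area(hull) - union) / area(hull)
  ca <- c((a[1] + a[3]) / 2, (a[2] + a[4]) / 2)
  cb <- c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)
  d2 <- sum((ca - cb)^2)
  c2 <- (hull[3] - hull[1])^2 + (hull[4] - hull[2])^2
  wa <- a[3] - a[1]; ha <- a[4] - a[2]; wb <- b[3] - b[1]; hb <- b[4] - b[2]
  v <- 4 / pi^2 * (atan(wa / ha) - atan(wb / hb))^2
  alpha <- if (v == 0) 0 else v / ((1 - iou) + v)
  list(iou = iou, giou = giou, v = v,
       ciou_loss = 1 - iou + d2 / c2 + alpha * v)
}

corner_of <- function(b) c(b[["cx"]] - b[["w"]] / 2, b[["cy"]] - b[["h"]] / 2,
                           b[["cx"]] + b[["w"]] / 2, b[["cy"]] + b[["h"]] / 2)

random_bbox <- function() {
  w <- runif(1, 0.02, 0.6); h <- runif(1, 0.02, 0.6)
  bbox(runif(1, w / 2, 1 - w / 2), runif(1, h / 2, 1 - h / 2), w, h)
}

# exhaustive assignment search over all column permutations
oracle_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- Inf; best_p <- NULL
  rec <- function(pre, rest) {
    if (length(pre) == nr) {
      tot <- sum(cost[cbind(seq_len(nr), pre)])
      if (tot < best) { best <<- tot; best_p <<- pre }
      return(invisible(NULL))
    }
    for (r in rest) rec(c(pre, r), setdiff(rest, r))
  }
  rec(integer(0), seq_len(nc))
  list(total_cost = best, assignment = best_p)
}

# numeric gradient of f at x by central differences
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
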