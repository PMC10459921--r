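# Bounding-box overlap measures (IOU, GIOU, CIOU), the combined border
# loss, and optimal bipartite (Hungarian) matching for set prediction.
# Currency: normalized center-format boxes (cx, cy, w, h) in [0, 1].

#' Normalized center-format bounding box
#'
#' @param cx,cy box center in `[0, 1]`.
#' @param w,h box extents, strictly positive.
#' @returns named numeric vector of class `bbox`.
#' @export
bbox <- function(cx, cy, w, h) {
  if (w <= 0 || h <= 0) stop("degenerate box: w and h must be positive")
  structure(c(cx = as.numeric(cx), cy = as.numeric(cy),
              w = as.numeric(w), h = as.numeric(h)), class = "bbox")
}

validate_box <- function(b) {
  b <- unclass(b)
  if (length(b) != 4 || any(!is.finite(b))) stop("malformed box")
  if (b[["w"]] <= 0 || b[["h"]] <= 0) stop("degenerate box: w and h must be positive")
  b
}

# corner form (x0, y0, x1, y1)
box_corners <- function(b) {
  c(b[["cx"]] - b[["w"]] / 2, b[["cy"]] - b[["h"]] / 2,
    b[["cx"]] + b[["w"]] / 2, b[["cy"]] + b[["h"]] / 2)
}

intersection_area <- function(a, b) {
  ca <- box_corners(a); cb <- box_corners(b)
  iw <- min(ca[3], cb[3]) - max(ca[1], cb[1])
  ih <- min(ca[4], cb[4]) - max(ca[2], cb[2])
  if (iw <= 0 || ih <= 0) 0 else iw * ih
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes as [bbox()] or `(cx, cy, w, h)` vectors.
#' @returns IOU in `[0, 1]`; symmetric in its arguments.
#' @export
#' @examples
#' iou(bbox(.25, .25, .5, .5), bbox(.5, .5, .5, .5))  # 1/7
iou <- function(a, b) {
  a <- validate_box(a); b <- validate_box(b)
  inter <- intersection_area(a, b)
  inter / (a[["w"]] * a[["h"]] + b[["w"]] * b[["h"]] - inter)
}

#' Generalized IOU
#'
#' `IOU - (hull - union) / hull`, where the hull is the smallest enclosing
#' axis-aligned box. Distinguishes non-overlapping configurations that
#' plain IOU maps to zero.
#'
#' @inheritParams iou
#' @returns GIOU in `(-1, 1]`.
#' @export
giou <- function(a, b) {
  a <- validate_box(a); b <- validate_box(b)
  inter <- intersection_area(a, b)
  union <- a[["w"]] * a[["h"]] + b[["w"]] * b[["h"]] - inter
  ca <- box_corners(a); cb <- box_corners(b)
  hull <- (max(ca[3], cb[3]) - min(ca[1], cb[1])) *
          (max(ca[4], cb[4]) - min(ca[2], cb[2]))
  inter / union - (hull - union) / hull
}

#' Aspect-ratio consistency term of the CIOU loss
#'
#' `v = (4 / pi^2) (arctan(w1/h1) - arctan(w/h))^2` where `(w1, h1)` is
#' the real (target) box and `(w, h)` the detected box. Zero when the
#' aspect ratios agree; at most 1.
#'
#' @param target,pred boxes (target = real box, pred = detected box).
#' @returns v in `[0, 1]`.
#' @export
ciou_aspect_term <- function(target, pred) {
  t <- validate_box(target); p <- validate_box(pred)
  (4 / pi^2) * (atan(t[["w"]] / t[["h"]]) - atan(p[["w"]] / p[["h"]]))^2
}

#' Complete-IOU loss
#'
#' `L = 1 - IOU + D^2 / C^2 + a v`, with `D` the Euclidean distance
#' between box centers, `C` the diagonal of the smallest enclosing box,
#' `v` the aspect term ([ciou_aspect_term()]) and the trade-off weight
#' `a = v / ((1 - IOU) + v)`. When `IOU = 1` and `v = 0` the `a v` term is
#' defined as 0. Penalizes center offset and aspect mismatch even when the
#' boxes do not intersect, which is what makes it converge faster than
#' GIOU for distant box pairs.
#'
#' @inheritParams ciou_aspect_term
#' @returns nonnegative loss; 0 iff the boxes coincide.
#' @export
ciou_loss <- function(target, pred) {
  t <- validate_box(target); p <- validate_box(pred)
  i <- iou(t, p)
  v <- ciou_aspect_term(t, p)
  d2 <- (t[["cx"]] - p[["cx"]])^2 + (t[["cy"]] - p[["cy"]])^2
  ct <- box_corners(t); cp <- box_corners(p)
  c2 <- (max(ct[3], cp[3]) - min(ct[1], cp[1]))^2 +
        (max(ct[4], cp[4]) - min(ct[2], cp[2]))^2
  av <- if (v == 0) 0 else v^2 / ((1 - i) + v)
  1 - i + d2 / c2 + av
}

#' Combined border loss: weighted CIOU + L1
#'
#' `lambda_ciou * Lciou + lambda_l1 * sum(|coordinate difference|)` with
#' the L1 taken over `(cx, cy, w, h)`.
#'
#' @inheritParams ciou_aspect_term
#' @param weights list/vector with `lambda_ciou` and `lambda_l1`
#'   (defaults 2 and 5, the conventional set-prediction weighting).
#' @returns nonnegative loss.
#' @export
box_loss <- function(target, pred, weights = loss_weights()) {
  t <- validate_box(target); p <- validate_box(pred)
  weights$lambda_ciou * ciou_loss(t, p) +
    weights$lambda_l1 * sum(abs(t - p))
}

#' Loss weights for the combined border loss
#' @param lambda_ciou,lambda_l1 nonnegative weights, not both zero.
#' @export
loss_weights <- function(lambda_ciou = 2, lambda_l1 = 5) {
  if (lambda_ciou < 0 || lambda_l1 < 0 || (lambda_ciou == 0 && lambda_l1 == 0))
    stop("weights must be nonnegative and not both zero")
  list(lambda_ciou = lambda_ciou, lambda_l1 = lambda_l1)
}

#' Optimal assignment of targets to predictions (Hungarian algorithm)
#'
#' Minimizes the total cost of an injective assignment of rows (targets)
#' to columns (predictions) via shortest augmenting paths with potentials
#' (Jonker-Volgenant). Requires at least as many columns as rows.
#'
#' @param cost numeric matrix, targets x predictions, finite entries.
#' @returns object of class `match_result`: `assignment` (integer vector,
#'   `assignment[i]` = prediction index for target i) and `total_cost`.
#' @export
#' @examples
#' hungarian_match(matrix(c(1, 10, 10, 1), 2, 2))$assignment  # 1 2
hungarian_match <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0)
    return(structure(list(assignment = integer(0), total_cost = 0),
                     class = "match_result"))
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  if (nc < nr) stop("need at least as many predictions (columns) as targets (rows)")
  INF <- sum(abs(cost)) + 1
  # shortest augmenting path per row, with dual potentials u, v
  u <- numeric(nr + 1); v <- numeric(nc + 1)
  way <- integer(nc + 1)
  col_of <- integer(nc + 1)       # col_of[j] = row assigned to column j (0 = free)
  for (i in seq_len(nr)) {
    col_of[1] <- i
    j0 <- 1L                      # position 1 is a virtual column
    minv <- rep(INF, nc + 1)
    used <- rep(FALSE, nc + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- col_of[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(nc + 1)) if (!used[j]) {
        cur <- cost[i0, j - 1] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(nc + 1)) {
        if (used[j]) { u[col_of[j]] <- u[col_of[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (col_of[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      col_of[j0] <- col_of[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(nr)
  for (j in 2:(nc + 1)) if (col_of[j] > 0) assignment[col_of[j]] <- j - 1L
  structure(list(assignment = assignment,
                 total_cost = sum(cost[cbind(seq_len(nr), assignment)])),
            class = "match_result")
}

#' Convert normalized center boxes to COCO pixel boxes and back
#'
#' COCO convention: `[x, y, w, h]` in pixels, top-left origin, 0-based.
#'
#' @param b a [bbox()] (or matrix with columns cx, cy, w, h).
#' @param side image side in pixels.
#' @returns numeric vector/matrix `[x, y, w, h]` in pixels.
#' @export
bbox_to_coco <- function(b, side) {
  if (is.matrix(b))
    return(cbind(x = (b[, 1] - b[, 3] / 2) * side, y = (b[, 2] - b[, 4] / 2) * side,
                 w = b[, 3] * side, h = b[, 4] * side))
  b <- validate_box(b)
  c(x = (b[["cx"]] - b[["w"]] / 2) * side, y = (b[["cy"]] - b[["h"]] / 2) * side,
    w = b[["w"]] * side, h = b[["h"]] * side)
}

#' @rdname bbox_to_coco
#' @param xywh COCO pixel box `[x, y, w, h]`.
#' @export
coco_to_bbox <- function(xywh, side) {
  bbox((xywh[[1]] + xywh[[3]] / 2) / side, (xywh[[2]] + xywh[[4]] / 2) / side,
       xywh[[3]] / side, xywh[[4]] / side)
}
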