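#' Construct a table of center-form bounding boxes
#'
#' Boxes follow the annotation convention of field pest datasets: a pest
#' instance is `(x, y, w, h, kappa)` where `(x, y)` is the box center, `(w, h)`
#' its width and height in pixels, and `kappa` the class label. A detection
#' additionally carries a confidence score in `[0, 1]`.
#'
#' Internally all area arithmetic treats a box as the half-open rectangle
#' `[cx - w/2, cx + w/2) x [cy - h/2, cy + h/2)` in continuous pixel
#' coordinates, which avoids the off-by-one ambiguities of integer-endpoint
#' conventions.
#'
#' @param cx,cy box center coordinates (pixels)
#' @param w,h box width and height (pixels, strictly positive)
#' @param label class label (character or integer); `NA` allowed
#' @param score optional confidence in `[0, 1]`; `NA` for ground truth
#' @return a `data.frame` with columns `cx, cy, w, h, label, score`
#' @examples
#' b <- boxes(cx = 20, cy = 40, w = 20, h = 40, label = "OF")
#' box_iou(b, b) # 1
#' @export
boxes <- function(cx = numeric(), cy = numeric(), w = numeric(),
                  h = numeric(), label = NA, score = NA_real_) {
  n <- length(cx)
  df <- data.frame(cx = as.numeric(cx), cy = as.numeric(cy),
                   w = as.numeric(w), h = as.numeric(h),
                   label = rep_len(label, n), score = rep_len(score, n),
                   stringsAsFactors = FALSE)
  validate_boxes(df)
  df
}

validate_boxes <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(!is.finite(df$w)) || any(!is.finite(df$h)) ||
      any(df$w <= 0) || any(df$h <= 0)) {
    stop("invalid box: width and height must be positive and finite")
  }
  sc <- df$score[!is.na(df$score)]
  if (any(sc < 0 | sc > 1)) stop("box scores must lie in [0, 1]")
  invisible(df)
}

#' Convert between center form and corner form
#'
#' Corner form is `(x1, y1, x2, y2)` with `x2 = x1 + w`, `y2 = y1 + h`
#' (half-open continuous rectangle).
#'
#' @param df a boxes data.frame (center form)
#' @return matrix with columns `x1, y1, x2, y2`
#' @export
box_corners <- function(df) {
  cbind(x1 = df$cx - df$w / 2, y1 = df$cy - df$h / 2,
        x2 = df$cx + df$w / 2, y2 = df$cy + df$h / 2)
}

#' @rdname box_corners
#' @param x1,y1,x2,y2 corner coordinates with `x2 > x1`, `y2 > y1`
#' @param label,score as in [boxes()]
#' @export
boxes_from_corners <- function(x1, y1, x2, y2, label = NA,
                               score = NA_real_) {
  boxes(cx = (x1 + x2) / 2, cy = (y1 + y2) / 2, w = x2 - x1, h = y2 - y1,
        label = label, score = score)
}

#' Intersection over union of two boxes
#'
#' `IoU = area(G intersect P) / area(G union P)` for a ground-truth box `G`
#' and predicted box `P`; the standard overlap criterion for deciding whether
#' a detection hits a ground-truth pest. Symmetric in its arguments and
#' always in `[0, 1]`.
#'
#' @param a,b boxes data.frames; rows are paired (recycled if one has 1 row)
#' @return numeric vector of IoU values
#' @examples
#' a <- boxes_from_corners(0, 0, 10, 10)
#' b <- boxes_from_corners(5, 0, 15, 10)
#' box_iou(a, b) # 50 / 150
#' @export
box_iou <- function(a, b) {
  validate_boxes(a)
  validate_boxes(b)
  ca <- box_corners(a)
  cb <- box_corners(b)
  n <- max(nrow(ca), nrow(cb))
  ia <- rep_len(seq_len(nrow(ca)), n)
  ib <- rep_len(seq_len(nrow(cb)), n)
  ca <- ca[ia, , drop = FALSE]
  cb <- cb[ib, , drop = FALSE]
  iw <- pmax(0, pmin(ca[, "x2"], cb[, "x2"]) - pmax(ca[, "x1"], cb[, "x1"]))
  ih <- pmax(0, pmin(ca[, "y2"], cb[, "y2"]) - pmax(ca[, "y1"], cb[, "y1"]))
  inter <- iw * ih
  union <- (ca[, "x2"] - ca[, "x1"]) * (ca[, "y2"] - ca[, "y1"]) +
    (cb[, "x2"] - cb[, "x1"]) * (cb[, "y2"] - cb[, "y1"]) - inter
  unname(inter / union)
}

# all-pairs IoU: rows of A vs rows of B -> nrow(A) x nrow(B) matrix
iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(matrix(0, nrow(a), nrow(b)))
  }
  ca <- box_corners(a)
  cb <- box_corners(b)
  iw <- pmax(0, outer(ca[, "x2"], cb[, "x2"], pmin) -
               outer(ca[, "x1"], cb[, "x1"], pmax))
  ih <- pmax(0, outer(ca[, "y2"], cb[, "y2"], pmin) -
               outer(ca[, "y1"], cb[, "y1"], pmax))
  inter <- iw * ih
  aa <- (ca[, "x2"] - ca[, "x1"]) * (ca[, "y2"] - ca[, "y1"])
  ab <- (cb[, "x2"] - cb[, "x1"]) * (cb[, "y2"] - cb[, "y1"])
  inter / (outer(aa, ab, "+") - inter)
}

# clip corner-form boxes (matrix x1,y1,x2,y2) to [0,w] x [0,h]
clip_corners <- function(m, img_w, img_h) {
  m[, "x1"] <- pmin(pmax(m[, "x1"], 0), img_w)
  m[, "x2"] <- pmin(pmax(m[, "x2"], 0), img_w)
  m[, "y1"] <- pmin(pmax(m[, "y1"], 0), img_h)
  m[, "y2"] <- pmin(pmax(m[, "y2"], 0), img_h)
  m
}
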