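# Anchor generation and box-delta parameterization for the region proposal
# network and the per-region heads. Anchors live in image pixel coordinates,
# corner form (x1, y1, x2, y2); regression targets are the standard
# log-space deltas (dx, dy, dw, dh) relative to an anchor or proposal.

# anchors for one pyramid level, in the exact linear order of the RPN
# output array (H, W, A): h fastest, then w, then anchor index
level_anchors <- function(H, W, stride, scales, ratios) {
  A <- length(scales) * length(ratios)
  hs <- seq_len(H)
  ws <- seq_len(W)
  cy <- rep((hs - 0.5) * stride, times = W)
  cx <- rep((ws - 0.5) * stride, each = H)
  out <- matrix(0, H * W * A, 4)
  i <- 0L
  for (sc in scales) {
    for (ra in ratios) {
      aw <- stride * sc * sqrt(ra)
      ah <- stride * sc / sqrt(ra)
      rows <- i * H * W + seq_len(H * W)
      out[rows, ] <- cbind(cx - aw / 2, cy - ah / 2, cx + aw / 2,
                           cy + ah / 2)
      i <- i + 1L
    }
  }
  colnames(out) <- c("x1", "y1", "x2", "y2")
  out
}

# corner-form matrix -> center form (cx, cy, w, h)
corners_to_center <- function(m) {
  cbind(cx = (m[, 1] + m[, 3]) / 2, cy = (m[, 2] + m[, 4]) / 2,
        w = m[, 3] - m[, 1], h = m[, 4] - m[, 2])
}

center_to_corners <- function(m) {
  cbind(x1 = m[, 1] - m[, 3] / 2, y1 = m[, 2] - m[, 4] / 2,
        x2 = m[, 1] + m[, 3] / 2, y2 = m[, 2] + m[, 4] / 2)
}

# encode ground-truth boxes (corner form) as deltas from anchors
encode_deltas <- function(anchors, gt) {
  a <- corners_to_center(anchors)
  g <- corners_to_center(gt)
  cbind(dx = (g[, "cx"] - a[, "cx"]) / a[, "w"],
        dy = (g[, "cy"] - a[, "cy"]) / a[, "h"],
        dw = log(g[, "w"] / a[, "w"]),
        dh = log(g[, "h"] / a[, "h"]))
}

# apply deltas to anchors; clamp dw/dh to avoid overflow on wild outputs
decode_deltas <- function(anchors, deltas, clamp = 4) {
  a <- corners_to_center(anchors)
  dw <- pmin(pmax(deltas[, 3], -clamp), clamp)
  dh <- pmin(pmax(deltas[, 4], -clamp), clamp)
  cx <- a[, "cx"] + deltas[, 1] * a[, "w"]
  cy <- a[, "cy"] + deltas[, 2] * a[, "h"]
  w <- a[, "w"] * exp(dw)
  h <- a[, "h"] * exp(dh)
  center_to_corners(cbind(cx, cy, w, h))
}

# all-pairs IoU between corner-form matrices
corner_iou_matrix <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(0, nrow(a), nrow(b)))
  iw <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  ih <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- iw * ih
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(aa, ab, "+") - inter)
}
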