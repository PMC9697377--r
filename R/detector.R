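# ---------------------------------------------------------------------------
# Two-stage detector: deformable residual backbone + attention fusion
# pyramid + region proposal network + per-region classification and
# box-regression heads. Training follows the standard two-stage recipe:
# anchors are labelled by IoU against ground truth and sampled into a
# balanced objectness batch; proposals (plus the ground-truth boxes, during
# training) are pooled with ROI-align, pushed through two fully connected
# layers, and end in a (c+1)-way softmax classification layer and a
# 4c-output localization layer.
# ---------------------------------------------------------------------------

#' Detector configuration
#'
#' `preset = "tiny"` (default) is the CPU-scale configuration used
#' throughout the tests and worked examples: a compact residual backbone
#' with deformable stages C4--C5, a 32-channel pyramid, and small sampling
#' batches. `preset = "full"` follows the conventional large-detector
#' hyperparameters (50-layer backbone, 256-channel pyramid); it builds and
#' runs but is not sized for desk-scale training.
#'
#' @param num_classes number of pest classes `c` (background handled
#'   internally as class `c + 1`)
#' @param class_names optional class label vector (length `num_classes`)
#' @param preset `"tiny"` or `"full"`
#' @param seed integer seed controlling parameter init, data order and
#'   target sampling
#' @param ... overrides for any configuration field
#' @return list of class `detector_config`
#' @export
detector_config <- function(num_classes, class_names = NULL,
                            preset = c("tiny", "full"), seed = 0L, ...) {
  preset <- match.arg(preset)
  stopifnot(num_classes >= 1)
  if (is.null(class_names)) class_names <- as.character(seq_len(num_classes))
  stopifnot(length(class_names) == num_classes)
  base <- if (preset == "tiny") {
    list(backbone = backbone_config("tiny", deformable_stages = c("C4", "C5")),
         neck = neck_config(d = 32L, hidden = 8L),
         pool_size = 4L, head_hidden = 64L,
         rpn_pre_nms = 200L, rpn_post_nms = 40L)
  } else {
    list(backbone = backbone_config("resnet50"),
         neck = neck_config(d = 256L),
         pool_size = 7L, head_hidden = 1024L,
         rpn_pre_nms = 1000L, rpn_post_nms = 300L)
  }
  cfg <- c(base, list(
    num_classes = as.integer(num_classes), class_names = class_names,
    anchor_scales = 4, anchor_ratios = c(0.5, 1, 2),
    levels = c("P2", "P3", "P4", "P5", "P6"),
    rpn_nms_thresh = 0.7, rpn_pos_iou = 0.7, rpn_neg_iou = 0.3,
    rpn_batch = 64L, rpn_pos_frac = 0.5,
    roi_batch = 32L, roi_pos_iou = 0.5, roi_pos_frac = 0.25,
    score_thresh = 0.05, nms_thresh = 0.5, max_dets = 50L,
    loss_weights = c(rpn_cls = 1, rpn_box = 1, roi_cls = 1, roi_box = 1),
    lr = 0.02, momentum = 0.9, weight_decay = 1e-4, clip = 10,
    warmup = 50L, epochs = 5L, seed = as.integer(seed)))
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "detector_config")
}

#' Build an untrained detector
#'
#' Parameter initialization is driven by `cfg$seed`.
#'
#' @param cfg a [detector_config()]
#' @return object of class `pd_detector`
#' @export
build_detector <- function(cfg) {
  stopifnot(inherits(cfg, "detector_config"))
  withr::with_seed(cfg$seed, {
    bb <- build_backbone(cfg$backbone)
    chan <- cfg$neck$d
    in_ch <- as.list(stats::setNames(bb$out_channels,
                                     c("C2", "C3", "C4", "C5")))
    neck <- build_neck(in_ch, cfg$neck)
    A <- length(cfg$anchor_scales) * length(cfg$anchor_ratios)
    rpn <- list(conv = conv_layer(chan, chan, k = 3, name = "rpn.conv"),
                cls = conv_layer(chan, A, k = 1, pad = 0, gain = 0.1,
                                 name = "rpn.cls"),
                box = conv_layer(chan, 4 * A, k = 1, pad = 0, gain = 0.1,
                                 name = "rpn.box"))
    din <- chan * cfg$pool_size^2
    c1 <- cfg$num_classes + 1L
    head <- list(fc1 = linear_layer(din, cfg$head_hidden, name = "head.fc1"),
                 fc2 = linear_layer(cfg$head_hidden, cfg$head_hidden,
                                    name = "head.fc2"),
                 cls = linear_layer(cfg$head_hidden, c1, name = "head.cls"),
                 box = linear_layer(cfg$head_hidden, 4L * cfg$num_classes,
                                    name = "head.box"))
    head$cls$w$v <- head$cls$w$v * 0.1
    head$box$w$v <- head$box$w$v * 0.1
    structure(list(backbone = bb, neck = neck, rpn = rpn, head = head,
                   cfg = cfg),
              class = "pd_detector")
  })
}

level_strides <- c(P2 = 4L, P3 = 8L, P4 = 16L, P5 = 32L, P6 = 64L)

# full forward pass on a tape: features, pyramid, RPN maps
forward_rpn_t <- function(tape, model, image, bypass = FALSE) {
  x <- td_const(image - 0.5)
  feats <- forward_backbone_t(tape, model$backbone, x)
  nk <- forward_neck_t(tape, model$neck, feats, bypass = bypass)
  rpn <- list()
  for (nm in model$cfg$levels) {
    h <- op_relu(tape, apply_conv(tape, model$rpn$conv, nk$P[[nm]]))
    rpn[[nm]] <- list(logits = apply_conv(tape, model$rpn$cls, h),
                      deltas = apply_conv(tape, model$rpn$box, h))
  }
  list(P = nk$P, alpha = nk$alpha, rpn = rpn)
}

# (H, W, 4A) delta array -> (H*W*A) x 4 matrix in anchor order
deltas_to_matrix <- function(arr) {
  d <- dim(arr)
  A <- d[3] %/% 4L
  out <- matrix(0, d[1] * d[2] * A, 4)
  for (a in seq_len(A)) {
    rows <- (a - 1L) * d[1] * d[2] + seq_len(d[1] * d[2])
    for (k in 1:4) out[rows, k] <- as.vector(arr[, , 4L * (a - 1L) + k])
  }
  out
}

# proposals from RPN values (no gradients), image size iw x ih
proposals_from_rpn <- function(rpn_vals, cfg, iw, ih) {
  per <- lapply(names(rpn_vals), function(nm) {
    lg <- rpn_vals[[nm]]$logits
    dl <- rpn_vals[[nm]]$deltas
    d <- dim(lg)
    anc <- level_anchors(d[1], d[2], level_strides[[nm]],
                         cfg$anchor_scales, cfg$anchor_ratios)
    sc <- stats::plogis(as.vector(lg))
    bx <- decode_deltas(anc, deltas_to_matrix(dl))
    bx <- clip_corners(bx, iw, ih)
    ok <- (bx[, "x2"] - bx[, "x1"]) >= 1 & (bx[, "y2"] - bx[, "y1"]) >= 1
    bx <- bx[ok, , drop = FALSE]
    sc <- sc[ok]
    if (nrow(bx) > cfg$rpn_pre_nms) {
      top <- order(sc, decreasing = TRUE, method = "radix")[
        seq_len(cfg$rpn_pre_nms)]
      bx <- bx[top, , drop = FALSE]
      sc <- sc[top]
    }
    cbind(bx, score = sc, level = which(names(level_strides) == nm))
  })
  all <- do.call(rbind, per)
  if (nrow(all) == 0) return(all)
  keep <- cpp_nms(all[, 1:4, drop = FALSE], all[, "score"],
                  cfg$rpn_nms_thresh)
  keep <- keep[seq_len(min(length(keep), cfg$rpn_post_nms))]
  all[keep, , drop = FALSE]
}

#' Generate region proposals from a feature pyramid
#'
#' Runs the region proposal network over every pyramid level, decodes the
#' per-anchor box deltas, clips to the image, and applies objectness
#' non-maximum suppression. Deterministic given fixed parameters.
#'
#' @param pyramid a `pyramid_features` object (see [build_pyramid()])
#' @param model a `pd_detector` (its RPN parameters are used)
#' @param image_size `c(width, height)` of the source image
#' @return data.frame with corner coordinates, `score`, and source `level`
#'   (at most `cfg$rpn_post_nms` rows)
#' @export
generate_proposals <- function(pyramid, model, image_size) {
  if (is.null(pyramid$levels) || length(pyramid$levels) == 0) {
    stop("empty pyramid")
  }
  tape <- td_tape()
  cfg <- model$cfg
  rpn_vals <- list()
  for (nm in cfg$levels) {
    P <- td_const(fm_values(pyramid$levels[[nm]]))
    h <- op_relu(tape, apply_conv(tape, model$rpn$conv, P))
    rpn_vals[[nm]] <- list(logits = apply_conv(tape, model$rpn$cls, h)$v,
                           deltas = apply_conv(tape, model$rpn$box, h)$v)
  }
  m <- proposals_from_rpn(rpn_vals, cfg, image_size[1], image_size[2])
  data.frame(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4],
             score = m[, "score"],
             level = names(level_strides)[m[, "level"]],
             stringsAsFactors = FALSE)
}

#' Per-region classification and localization heads
#'
#' Two fully connected layers followed by a classification layer with
#' `c + 1` outputs (softmax over the pest classes plus background) and a
#' localization layer with `4c` outputs.
#'
#' @param region_feats pooled region features: (p, p, d, n) array or an
#'   `n x (p*p*d)` matrix
#' @param model a `pd_detector`
#' @return list with `scores` (`n x (c+1)`, rows sum to 1) and `deltas`
#'   (`n x 4c`)
#' @export
roi_head <- function(region_feats, model) {
  cfg <- model$cfg
  din <- cfg$neck$d * cfg$pool_size^2
  x <- if (is.matrix(region_feats)) region_feats else {
    d <- dim(region_feats)
    t(matrix(region_feats, nrow = prod(d[1:3]), ncol = d[4]))
  }
  if (ncol(x) != din) {
    stop("pooled feature size mismatch: expected ", din, " values per ",
         "region, got ", ncol(x))
  }
  tape <- td_tape()
  out <- roi_head_t(tape, model, td_const(x))
  z <- out$cls$v
  zm <- z - apply(z, 1, max)
  ez <- exp(zm)
  list(scores = ez / rowSums(ez), deltas = out$box$v)
}

roi_head_t <- function(tape, model, x) {
  h <- op_relu(tape, apply_linear(tape, model$head$fc1, x))
  h <- op_relu(tape, apply_linear(tape, model$head$fc2, h))
  list(cls = apply_linear(tape, model$head$cls, h),
       box = apply_linear(tape, model$head$box, h))
}

# row-bind matrix tensors
op_rbind <- function(tape, xs) {
  ns <- vapply(xs, function(t) nrow(t$v), 1L)
  ends <- cumsum(ns)
  starts <- c(1L, head(ends, -1L) + 1L)
  td_node(do.call(rbind, lapply(xs, function(t) t$v)), tape,
          bw = function(g) {
            for (i in seq_along(xs)) {
              acc_grad(xs[[i]], g[starts[i]:ends[i], , drop = FALSE])
            }
          })
}

# assign each ROI (corner form) to a pyramid level by object size
assign_roi_levels <- function(m, cfg) {
  size <- sqrt(pmax((m[, 3] - m[, 1]) * (m[, 4] - m[, 2]), 1e-6))
  tgt <- log2(size / cfg$anchor_scales[1])
  lv <- round(tgt - log2(level_strides[cfg$levels[1]]) ) + 1L
  pmin(pmax(lv, 1L), length(cfg$levels))
}

# pooled features for ROIs grouped by level -> single matrix tensor plus the
# permutation mapping rows back to the input ROI order
pool_rois_t <- function(tape, P, rois, cfg) {
  lv <- assign_roi_levels(rois, cfg)
  pieces <- list()
  perm <- integer(0)
  for (li in sort(unique(lv))) {
    nm <- cfg$levels[li]
    idx <- which(lv == li)
    s <- level_strides[[nm]]
    fr <- cbind(rois[idx, 2] / s, rois[idx, 1] / s,
                rois[idx, 4] / s, rois[idx, 3] / s)  # r1, c1, r2, c2
    pooled <- op_roialign(tape, P[[nm]], fr, cfg$pool_size, cfg$pool_size)
    pieces[[length(pieces) + 1]] <- op_flatten_rois(tape, pooled)
    perm <- c(perm, idx)
  }
  x <- if (length(pieces) == 1) pieces[[1]] else op_rbind(tape, pieces)
  list(x = x, perm = perm)
}

#' Detect pests in an image
#'
#' Full inference pass: backbone, fusion pyramid, region proposals, region
#' heads, per-class score thresholding and non-maximum suppression. Output
#' boxes are clipped to the image and reported in original pixel
#' coordinates, center form. Deterministic for fixed inputs and parameters.
#'
#' @param image (H, W, 3) array in `[0, 1]`, or a PNG file path
#' @param model a `pd_detector`
#' @param score_thresh,nms_thresh,max_dets optional overrides of the
#'   config values
#' @return boxes data.frame (`cx, cy, w, h, label, score`)
#' @export
detect <- function(image, model, score_thresh = NULL, nms_thresh = NULL,
                   max_dets = NULL) {
  if (is.character(image)) {
    if (!file.exists(image)) stop("cannot read image: ", image)
    image <- load_scene_image(list(path = image))
  }
  cfg <- model$cfg
  score_thresh <- score_thresh %||% cfg$score_thresh
  nms_thresh <- nms_thresh %||% cfg$nms_thresh
  max_dets <- max_dets %||% cfg$max_dets
  ih <- dim(image)[1]
  iw <- dim(image)[2]
  tape <- td_tape()
  fw <- forward_rpn_t(tape, model, image)
  rpn_vals <- lapply(fw$rpn, function(l) list(logits = l$logits$v,
                                              deltas = l$deltas$v))
  prop <- proposals_from_rpn(rpn_vals, cfg, iw, ih)
  if (is.null(prop) || nrow(prop) == 0) return(boxes())
  pooled <- pool_rois_t(tape, fw$P, prop[, 1:4, drop = FALSE], cfg)
  out <- roi_head_t(tape, model, pooled$x)
  z <- out$cls$v
  zm <- z - apply(z, 1, max)
  ez <- exp(zm)
  probs <- ez / rowSums(ez)
  deltas <- out$box$v
  # rows of probs/deltas are in pooled (permuted) order
  rois <- prop[pooled$perm, 1:4, drop = FALSE]
  dets <- list()
  for (k in seq_len(cfg$num_classes)) {
    sc <- probs[, k]
    sel <- which(sc >= score_thresh)
    if (length(sel) == 0) next
    bx <- decode_deltas(as.matrix(rois[sel, , drop = FALSE]),
                        deltas[sel, 4 * (k - 1) + 1:4, drop = FALSE])
    bx <- clip_corners(bx, iw, ih)
    ok <- (bx[, "x2"] - bx[, "x1"]) >= 1 & (bx[, "y2"] - bx[, "y1"]) >= 1
    if (!any(ok)) next
    bx <- bx[ok, , drop = FALSE]
    sck <- sc[sel][ok]
    keep <- cpp_nms(bx, sck, nms_thresh)
    dets[[length(dets) + 1]] <-
      data.frame(x1 = bx[keep, 1], y1 = bx[keep, 2], x2 = bx[keep, 3],
                 y2 = bx[keep, 4], score = sck[keep],
                 label = cfg$class_names[k], stringsAsFactors = FALSE)
  }
  if (length(dets) == 0) return(boxes())
  all <- do.call(rbind, dets)
  all <- all[order(all$score, decreasing = TRUE, method = "radix"),
             , drop = FALSE]
  all <- all[seq_len(min(nrow(all), max_dets)), , drop = FALSE]
  boxes_from_corners(all$x1, all$y1, all$x2, all$y2, label = all$label,
                     score = all$score)
}

# --- training ---------------------------------------------------------------

rpn_anchor_targets <- function(anchors, gt, cfg) {
  n <- nrow(anchors)
  labels <- rep(-1L, n)          # -1 ignore, 0 negative, 1 positive
  match_gt <- rep(NA_integer_, n)
  if (nrow(gt) == 0) {
    labels[] <- 0L
  } else {
    iou <- corner_iou_matrix(anchors, gt)
    best <- apply(iou, 1, max)
    besti <- apply(iou, 1, which.max)
    labels[best < cfg$rpn_neg_iou] <- 0L
    labels[best >= cfg$rpn_pos_iou] <- 1L
    # every ground-truth box gets its best anchor as a positive
    for (j in seq_len(nrow(gt))) {
      top <- which(iou[, j] >= max(iou[, j]) - 1e-9 & iou[, j] > 0)
      labels[top] <- 1L
      match_gt[top] <- j
    }
    match_gt[labels == 1L & is.na(match_gt)] <-
      besti[labels == 1L & is.na(match_gt)]
  }
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  n_pos <- min(length(pos), floor(cfg$rpn_batch * cfg$rpn_pos_frac))
  if (length(pos) > n_pos) pos <- sample(pos, n_pos)
  n_neg <- min(length(neg), cfg$rpn_batch - length(pos))
  if (length(neg) > n_neg) neg <- sample(neg, n_neg)
  list(pos = pos, neg = neg, match_gt = match_gt)
}

roi_targets <- function(rois, gt, gt_labels, cfg) {
  n <- nrow(rois)
  if (nrow(gt) == 0) {
    lab <- rep.int(cfg$num_classes + 1L, n)
    keep <- sample(seq_len(n), min(n, cfg$roi_batch))
    return(list(idx = keep, cls = lab[keep],
                box_tgt = NULL, pos_rows = integer(0)))
  }
  iou <- corner_iou_matrix(as.matrix(rois), gt)
  best <- apply(iou, 1, max)
  besti <- apply(iou, 1, which.max)
  pos <- which(best >= cfg$roi_pos_iou)
  neg <- which(best < cfg$roi_pos_iou)
  n_pos <- min(length(pos), max(1L, floor(cfg$roi_batch * cfg$roi_pos_frac)))
  if (length(pos) > n_pos) pos <- sample(pos, n_pos)
  n_neg <- min(length(neg), cfg$roi_batch - length(pos))
  if (length(neg) > n_neg) neg <- sample(neg, n_neg)
  idx <- c(pos, neg)
  cls <- c(gt_labels[besti[pos]], rep.int(cfg$num_classes + 1L,
                                          length(neg)))
  box_tgt <- if (length(pos) > 0) {
    encode_deltas(as.matrix(rois[pos, , drop = FALSE]),
                  gt[besti[pos], , drop = FALSE])
  } else NULL
  list(idx = idx, cls = cls, box_tgt = box_tgt,
       pos_rows = seq_along(pos))
}

# losses for one image; returns list of scalar tensors (or NULL entries)
image_losses <- function(tape, model, image, gt_corners, gt_labels) {
  cfg <- model$cfg
  ih <- dim(image)[1]
  iw <- dim(image)[2]
  fw <- forward_rpn_t(tape, model, image)
  # --- RPN targets over all levels ---
  anchors <- list()
  offs <- 0L
  meta <- list()
  for (nm in cfg$levels) {
    d <- dim(fw$rpn[[nm]]$logits$v)
    anc <- level_anchors(d[1], d[2], level_strides[[nm]],
                         cfg$anchor_scales, cfg$anchor_ratios)
    meta[[nm]] <- list(offset = offs, n = nrow(anc))
    offs <- offs + nrow(anc)
    anchors[[nm]] <- anc
  }
  all_anc <- do.call(rbind, anchors)
  tg <- rpn_anchor_targets(all_anc, gt_corners, cfg)
  sel <- c(tg$pos, tg$neg)
  sel_lab <- c(rep(1, length(tg$pos)), rep(0, length(tg$neg)))
  # gather logits per level
  gather_level <- function(tensor_field, idx_global, per_anchor = 1L) {
    pieces <- list()
    for (nm in cfg$levels) {
      m <- meta[[nm]]
      loc <- idx_global[idx_global > m$offset & idx_global <= m$offset + m$n] -
        m$offset
      if (length(loc) == 0) next
      ten <- fw$rpn[[nm]][[tensor_field]]
      if (per_anchor == 1L) {
        pieces[[length(pieces) + 1]] <- op_gather(tape, ten, loc)
      } else {
        d <- dim(ten$v)
        HW <- d[1] * d[2]
        a <- (loc - 1L) %/% HW       # anchor index 0-based
        p <- (loc - 1L) %% HW        # spatial position 0-based
        idx4 <- as.vector(vapply(seq_along(loc), function(i) {
          p[i] + HW * (4L * a[i] + 0:3) + 1L
        }, integer(4)))
        pieces[[length(pieces) + 1]] <- op_gather(tape, ten, idx4)
      }
    }
    if (length(pieces) == 0) return(NULL)
    if (length(pieces) == 1) pieces[[1]] else op_concat(tape, pieces)
  }
  losses <- list()
  ord <- order(sel)
  if (length(sel) > 0) {
    lg <- gather_level("logits", sel[ord])
    losses$rpn_cls <- op_bce_logits(tape, lg, sel_lab[ord])
  }
  if (length(tg$pos) > 0 && nrow(gt_corners) > 0) {
    poso <- sort(tg$pos)
    dl <- gather_level("deltas", poso, per_anchor = 4L)
    tgt <- encode_deltas(all_anc[poso, , drop = FALSE],
                         gt_corners[tg$match_gt[poso], , drop = FALSE])
    # gather order is (dx,dy,dw,dh) per anchor, anchors in poso order
    losses$rpn_box <- op_smooth_l1(tape, dl, as.vector(t(tgt)),
                                   norm = max(1, length(sel)))
  }
  # --- proposals + ROI head ---
  rpn_vals <- lapply(fw$rpn, function(l) list(logits = l$logits$v,
                                              deltas = l$deltas$v))
  prop <- proposals_from_rpn(rpn_vals, cfg, iw, ih)
  rois <- rbind(if (!is.null(prop) && nrow(prop) > 0)
                  prop[, 1:4, drop = FALSE] else NULL,
                gt_corners)
  if (!is.null(rois) && nrow(rois) > 0) {
    rt <- roi_targets(rois, gt_corners, gt_labels, cfg)
    sampled <- rois[rt$idx, , drop = FALSE]
    pooled <- pool_rois_t(tape, fw$P, sampled, cfg)
    out <- roi_head_t(tape, model, pooled$x)
    # targets follow the pooled permutation
    cls_t <- rt$cls[pooled$perm]
    losses$roi_cls <- op_softmax_ce(tape, out$cls, cls_t)
    if (length(rt$pos_rows) > 0) {
      pos_in_perm <- which(pooled$perm %in% rt$pos_rows)
      if (length(pos_in_perm) > 0) {
        rowmap <- match(pooled$perm[pos_in_perm], rt$pos_rows)
        k <- rt$cls[rt$pos_rows][rowmap]   # true class per pooled pos row
        cidx <- as.vector(vapply(seq_along(pos_in_perm), function(i) {
          r <- pos_in_perm[i]
          r + nrow(out$box$v) * (4L * (k[i] - 1L) + 0:3)
        }, integer(4)))
        pred <- op_gather(tape, out$box, cidx)
        tgt <- as.vector(t(rt$box_tgt[rowmap, , drop = FALSE]))
        losses$roi_box <- op_smooth_l1(tape, pred, tgt,
                                       norm = max(1, length(rt$idx)))
      }
    }
  }
  losses
}

#' Train a detector
#'
#' Stochastic gradient descent with momentum, one image per step, a linear
#' learning-rate warmup, and the standard two-stage losses (binary
#' cross-entropy + smooth L1 for the RPN; softmax cross-entropy + smooth L1
#' for the region heads). Reproducible for a fixed `cfg$seed`.
#'
#' @param dataset list of annotation records with `path` (or `image_array`)
#'   and `boxes`; labels must be in `cfg$class_names`
#' @param cfg a [detector_config()]
#' @param epochs number of passes over the data (default `cfg$epochs`)
#' @param resume optional checkpoint (see [save_checkpoint()]) to continue
#'   from
#' @param verbose print per-epoch loss lines
#' @return list of class `pd_trained`: `model`, `log` (per-epoch
#'   data.frame), `cfg`, `opt_state`
#' @export
train_detector <- function(dataset, cfg, epochs = NULL, resume = NULL,
                           verbose = FALSE) {
  n_ann <- sum(vapply(dataset, function(r) nrow(r$boxes), 1L))
  if (length(dataset) == 0 || n_ann == 0) {
    stop("dataset has no annotations; cannot train")
  }
  epochs <- epochs %||% cfg$epochs
  if (!is.null(resume)) {
    model <- load_checkpoint(resume)
    cfg <- model$cfg
    start_epoch <- attr(model, "epoch") + 1L
    log <- attr(model, "log")
    opt <- sgd_new(collect_params(model[c("backbone", "neck", "rpn",
                                          "head")]),
                   lr = cfg$lr, momentum = cfg$momentum, clip = cfg$clip,
                   weight_decay = cfg$weight_decay)
    if (!is.null(attr(model, "opt_buf"))) opt$buf <- attr(model, "opt_buf")
  } else {
    model <- build_detector(cfg)
    start_epoch <- 1L
    log <- NULL
    opt <- sgd_new(collect_params(model[c("backbone", "neck", "rpn",
                                          "head")]),
                   lr = cfg$lr, momentum = cfg$momentum, clip = cfg$clip,
                   weight_decay = cfg$weight_decay)
  }
  # preload images
  imgs <- lapply(dataset, function(r) {
    if (!is.null(r$image_array)) r$image_array else load_scene_image(r)
  })
  gts <- lapply(dataset, function(r) {
    list(corners = box_corners(r$boxes),
         labels = match(as.character(r$boxes$label), cfg$class_names))
  })
  if (any(vapply(gts, function(g) anyNA(g$labels), TRUE))) {
    stop("dataset contains labels outside cfg$class_names")
  }
  it <- (start_epoch - 1L) * length(dataset)
  for (ep in seq(start_epoch, length.out = epochs - start_epoch + 1L)) {
    set.seed((cfg$seed * 1009L + ep * 7919L) %% .Machine$integer.max)
    ord <- sample(length(dataset))
    comp <- c(rpn_cls = 0, rpn_box = 0, roi_cls = 0, roi_box = 0)
    tot <- 0
    nskip <- 0L
    for (i in ord) {
      it <- it + 1L
      tape <- td_tape()
      ls <- image_losses(tape, model, imgs[[i]], gts[[i]]$corners,
                         gts[[i]]$labels)
      if (length(ls) == 0) next
      w <- cfg$loss_weights[names(ls)]
      total <- op_wsum(tape, unname(ls), unname(w))
      if (!is.finite(total$v)) {
        nskip <- nskip + 1L
        zero_grads(opt$params)
        next
      }
      td_backward(total, tape)
      lr_scale <- if (it <= cfg$warmup) it / cfg$warmup else 1
      opt$lr <- cfg$lr * lr_scale
      opt <- sgd_step(opt)
      tot <- tot + total$v
      for (nm in names(ls)) comp[nm] <- comp[nm] + ls[[nm]]$v
    }
    row <- data.frame(epoch = ep, loss = tot / length(dataset),
                      rpn_cls = comp["rpn_cls"] / length(dataset),
                      rpn_box = comp["rpn_box"] / length(dataset),
                      roi_cls = comp["roi_cls"] / length(dataset),
                      roi_box = comp["roi_box"] / length(dataset),
                      skipped = nskip, row.names = NULL)
    log <- rbind(log, row)
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f (rpn %.3f/%.3f roi %.3f/%.3f)",
                      ep, row$loss, row$rpn_cls, row$rpn_box, row$roi_cls,
                      row$roi_box))
    }
  }
  structure(list(model = model, log = log, cfg = cfg,
                 opt_state = opt$buf),
            class = "pd_trained")
}

#' Save / load a detector checkpoint
#'
#' The checkpoint holds the configuration, all parameter values, the
#' optimizer momentum buffers and the training log, so training can resume
#' deterministically.
#'
#' @param trained a `pd_trained` (or a bare `pd_detector`)
#' @param path file path (RDS container)
#' @export
save_checkpoint <- function(trained, path) {
  if (inherits(trained, "pd_detector")) {
    trained <- list(model = trained, log = NULL, cfg = trained$cfg,
                    opt_state = NULL)
  }
  saveRDS(list(cfg = trained$cfg,
               weights = get_weights(trained$model[c("backbone", "neck",
                                                     "rpn", "head")]),
               log = trained$log, opt_state = trained$opt_state),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns a `pd_detector` with attributes
#'   `epoch`, `log` and `opt_buf`
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_detector(ck$cfg)
  set_weights(model[c("backbone", "neck", "rpn", "head")], ck$weights)
  attr(model, "epoch") <- if (is.null(ck$log)) 0L else max(ck$log$epoch)
  attr(model, "log") <- ck$log
  attr(model, "opt_buf") <- ck$opt_state
  model
}

#' Evaluate a trained detector on a dataset
#'
#' Runs [detect()] on every image and scores the detections against the
#' annotations with the full per-class AP stack.
#'
#' @param trained a `pd_trained` or `pd_detector`
#' @param dataset list of annotation records (with image paths or arrays)
#' @param ... passed to [evaluate()]
#' @return an `eval_report`
#' @export
evaluate_model <- function(trained, dataset, ...) {
  model <- if (inherits(trained, "pd_trained")) trained$model else trained
  dets <- list()
  gts <- list()
  for (i in seq_along(dataset)) {
    r <- dataset[[i]]
    img <- if (!is.null(r$image_array)) r$image_array else
      load_scene_image(r)
    d <- detect(img, model)
    if (nrow(d) > 0) {
      d$image <- r$image
      dets[[length(dets) + 1]] <- d
    }
    g <- r$boxes
    if (nrow(g) > 0) {
      g$image <- r$image
      gts[[length(gts) + 1]] <- g
    }
  }
  dd <- if (length(dets)) do.call(rbind, dets) else
    cbind(boxes(), image = character(0))
  gg <- if (length(gts)) do.call(rbind, gts) else
    cbind(boxes(), image = character(0))
  evaluate(dd, gg, classes = model$cfg$class_names, ...)
}
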