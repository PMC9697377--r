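# ---------------------------------------------------------------------------
# Deformable residual backbone.
#
# The deformable convolution computes, at each output location l0,
#     y(l0) = sum_{ln in Omega} w(ln) * x(l0 + ln + Delta_ln)
# where Omega is the 3x3 sampling grid and Delta_ln are 2-D offsets predicted
# per output position and per tap by an ordinary 3x3 convolution. Fractional
# sampling positions are read through the separable tent kernel
#     G(k, l) = max(0, 1 - |k_x - l_x|) * max(0, 1 - |k_y - l_y|),
# so positions more than one pixel outside the grid contribute zero.
# ---------------------------------------------------------------------------

#' A feature map with a known stride
#'
#' @param values (H, W, C) numeric array of activations
#' @param stride downsampling factor relative to the input image
#'   (one of 1, 2, 4, 8, 16, 32)
#' @return object of class `feature_map`
#' @export
feature_map <- function(values, stride = 1L) {
  stopifnot(length(dim(values)) == 3,
            stride %in% c(1L, 2L, 4L, 8L, 16L, 32L, 64L))
  structure(list(values = values, stride = as.integer(stride)),
            class = "feature_map")
}

fm_values <- function(x) if (inherits(x, "feature_map")) x$values else x

#' Bilinear sampling of a feature map at continuous locations
#'
#' Evaluates `sum_k G(k, l) x(k)` with the separable tent kernel `G`;
#' integer locations return the stored pixel exactly and locations more
#' than one pixel outside the grid return 0 (implicit zero padding).
#' Coordinates are zero-based with integer values at pixel centres:
#' `(x = 0, y = 0)` is the first pixel, `x` runs along columns.
#'
#' @param x a `feature_map` or (H, W, C) array
#' @param l numeric matrix with columns `x`, `y` (or a length-2 vector)
#' @param channel channel index (1-based), recycled over rows of `l`
#' @return numeric vector of sampled values
#' @export
bilinear_sample <- function(x, l, channel = 1L) {
  v <- fm_values(x)
  if (is.matrix(v)) v <- array(v, dim = c(dim(v), 1L))
  if (!is.matrix(l)) l <- matrix(l, ncol = 2, byrow = TRUE)
  if (any(!is.finite(l))) stop("sampling locations must be finite")
  ch <- rep_len(as.integer(channel), nrow(l))
  cpp_bilinear_sample(v, r = l[, 2], c = l[, 1], ch = ch)
}

#' Predict per-tap sampling offsets with an ordinary convolution
#'
#' The offset field is produced by a regular 3x3, dilation-1, stride-1,
#' pad-1 convolution, so its spatial size equals the input's. Its `2 * K`
#' channels hold, for each of the K kernel taps (in array order over the
#' kernel grid), the row offset then the column offset in pixels.
#'
#' @param x a `feature_map` or (H, W, C) array
#' @param offset_conv list with `w` ((3, 3, C, 2K) array) and optional `b`
#' @return (H, W, 2K) offset array
#' @export
predict_offsets <- function(x, offset_conv) {
  v <- fm_values(x)
  w <- offset_conv$w
  if (is_td(w)) w <- w$v
  b <- offset_conv$b
  if (is_td(b)) b <- b$v
  if (dim(w)[3] != dim(v)[3]) {
    stop("offset conv expects ", dim(w)[3], " input channels, got ",
         dim(v)[3])
  }
  if (dim(w)[4] %% 2 != 0) stop("offset conv must have 2*K output channels")
  cpp_conv2d_fwd(v, w, if (is.null(b)) numeric(0) else b, 1L, 1L, 1L)
}

#' Deformable 2-D convolution
#'
#' Each kernel tap samples the input at its regular grid position displaced
#' by a learned per-position offset, read through bilinear interpolation.
#' With all offsets zero this reduces exactly to a standard convolution.
#'
#' @param x `feature_map` or (H, W, Cin) array
#' @param w (kh, kw, Cin, Cout) weight array
#' @param offsets (Ho, Wo, 2*kh*kw) offset array (see [predict_offsets()])
#' @param bias optional length-Cout vector
#' @param stride,pad,dil convolution geometry
#' @return (Ho, Wo, Cout) array
#' @export
deformable_conv2d <- function(x, w, offsets, bias = NULL, stride = 1L,
                              pad = 1L, dil = 1L) {
  v <- fm_values(x)
  if (dim(w)[3] != dim(v)[3]) {
    stop("input channel mismatch: weights expect ", dim(w)[3], ", got ",
         dim(v)[3])
  }
  if (dim(offsets)[3] != 2 * dim(w)[1] * dim(w)[2]) {
    stop("offset field must have ", 2 * dim(w)[1] * dim(w)[2],
         " channels, got ", dim(offsets)[3])
  }
  if (any(!is.finite(offsets))) stop("offsets must be finite")
  cpp_deform_fwd(v, w, if (is.null(bias)) numeric(0) else bias, offsets,
                 as.integer(stride), as.integer(pad), as.integer(dil))
}

#' Backbone configuration
#'
#' @param depth `"tiny"` (a compact 4-stage residual net used for
#'   CPU-scale experiments), `"resnet18"`, or `"resnet50"`
#' @param deformable_stages which stages use deformable 3x3 convolutions;
#'   default C3--C5, the usual choice for deformable residual networks
#' @param deformable use deformable convolutions at all
#' @return list of class `backbone_config`
#' @export
backbone_config <- function(depth = "resnet50",
                            deformable_stages = c("C3", "C4", "C5"),
                            deformable = TRUE) {
  variants <- c("tiny", "resnet18", "resnet50")
  if (!depth %in% variants) {
    stop("unknown depth variant '", depth, "'; supported: ",
         paste(variants, collapse = ", "))
  }
  if (deformable && length(deformable_stages) == 0) {
    stop("deformable mode needs at least one deformable stage")
  }
  structure(list(depth = depth,
                 deformable_stages = if (deformable) deformable_stages
                                     else character(),
                 deformable = deformable),
            class = "backbone_config")
}

backbone_spec <- function(depth) {
  switch(depth,
    tiny = list(stem = 8, widths = c(8, 16, 24, 32), blocks = c(1, 1, 1, 1),
                bottleneck = FALSE, stem_k = 3),
    resnet18 = list(stem = 64, widths = c(64, 128, 256, 512),
                    blocks = c(2, 2, 2, 2), bottleneck = FALSE, stem_k = 7),
    resnet50 = list(stem = 64, widths = c(256, 512, 1024, 2048),
                    blocks = c(3, 4, 6, 3), bottleneck = TRUE, stem_k = 7))
}

make_block <- function(cin, cout, stride, deform, bottleneck, name) {
  if (bottleneck) {
    mid <- cout %/% 4
    inner <- conv_layer(cin, mid, k = 1, name = paste0(name, ".c1"))
    mk3 <- if (deform) deform_layer(mid, mid, stride = stride,
                                    name = paste0(name, ".c2"))
           else conv_layer(mid, mid, stride = stride,
                           name = paste0(name, ".c2"))
    outc <- conv_layer(mid, cout, k = 1, gain = 0.5,
                       name = paste0(name, ".c3"))
    layers <- list(inner, mk3, outc)
  } else {
    mk1 <- if (deform) deform_layer(cin, cout, stride = stride,
                                    name = paste0(name, ".c1"))
           else conv_layer(cin, cout, stride = stride,
                           name = paste0(name, ".c1"))
    mk2 <- if (deform) deform_layer(cout, cout, gain = 0.5,
                                    name = paste0(name, ".c2"))
           else conv_layer(cout, cout, gain = 0.5,
                           name = paste0(name, ".c2"))
    layers <- list(mk1, mk2)
  }
  short <- if (stride != 1 || cin != cout) {
    conv_layer(cin, cout, k = 1, stride = stride, pad = 0,
               name = paste0(name, ".sc"))
  } else NULL
  list(layers = layers, short = short, bottleneck = bottleneck)
}

apply_block <- function(tape, blk, x) {
  h <- x
  n <- length(blk$layers)
  for (i in seq_len(n)) {
    h <- apply_conv(tape, blk$layers[[i]], h)
    if (i < n) h <- op_relu(tape, h)
  }
  s <- if (is.null(blk$short)) x else apply_conv(tape, blk$short, x)
  op_relu(tape, op_add(tape, h, s))
}

#' Build a residual feature-extraction backbone
#'
#' Returns a multi-stage extractor producing feature maps C2--C5 at strides
#' 4, 8, 16, 32 relative to the input image. In the configured stages the
#' 3x3 convolutions are deformable; their offset-predicting convolutions are
#' zero-initialized, so a freshly built deformable backbone computes exactly
#' the same function as its regular counterpart.
#'
#' @param cfg a [backbone_config()]
#' @return object of class `pd_backbone` with elements `stem`, `stages`,
#'   `cfg`, `out_channels`; call [forward_backbone()] (or use it inside a
#'   detector) to run it
#' @export
build_backbone <- function(cfg = backbone_config()) {
  stopifnot(inherits(cfg, "backbone_config"))
  sp <- backbone_spec(cfg$depth)
  stem <- conv_layer(3, sp$stem, k = sp$stem_k, stride = 2, name = "stem")
  stages <- list()
  cin <- sp$stem
  for (si in 1:4) {
    stage_name <- paste0("C", si + 1)
    deform <- stage_name %in% cfg$deformable_stages
    blocks <- list()
    for (bi in seq_len(sp$blocks[si])) {
      stride <- if (si > 1 && bi == 1) 2 else 1
      blocks[[bi]] <- make_block(cin, sp$widths[si], stride, deform,
                                 sp$bottleneck,
                                 paste0(stage_name, ".b", bi))
      cin <- sp$widths[si]
    }
    stages[[stage_name]] <- blocks
  }
  structure(list(stem = stem, stages = stages, cfg = cfg,
                 out_channels = sp$widths),
            class = "pd_backbone")
}

# tape version used by the detector
forward_backbone_t <- function(tape, bb, x) {
  h <- op_relu(tape, apply_conv(tape, bb$stem, x))
  h <- op_maxpool2(tape, h)
  out <- list()
  for (nm in names(bb$stages)) {
    for (blk in bb$stages[[nm]]) h <- apply_block(tape, blk, h)
    out[[nm]] <- h
  }
  out
}

#' Run a backbone on an image
#'
#' @param bb a `pd_backbone`
#' @param image (H, W, 3) array in `[0, 1]`
#' @return named list of `feature_map`s C2--C5 at strides 4, 8, 16, 32
#' @export
forward_backbone <- function(bb, image) {
  tape <- td_tape()
  x <- td_const(image - 0.5)
  fs <- forward_backbone_t(tape, bb, x)
  strides <- c(C2 = 4L, C3 = 8L, C4 = 16L, C5 = 32L)
  mapply(function(f, nm) feature_map(f$v, strides[[nm]]),
         fs, names(fs), SIMPLIFY = FALSE)
}
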