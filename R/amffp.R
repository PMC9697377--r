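# ---------------------------------------------------------------------------
# Attention-weighted multi-scale feature-fusion pyramid.
#
# Plain FPN aggregates adjacent levels as  P_i = B_i(X_i) + alpha * Fup(P_{i+1})
# with the fusion factor alpha fixed at 1. Here alpha is instead produced per
# fused level by a small generator -- sigmoid(conv3x3(relu(conv1x1(.)))) --
# applied to the upsampled upper pathway, giving each pyramid level its own
# spatial weight map in (0, 1). Because a sigmoid never reaches 1 exactly,
# exact plain-FPN behaviour is exposed through an explicit bypass flag
# (alpha == 1), which is also what the equivalence tests use.
# ---------------------------------------------------------------------------

#' Neck (pyramid) configuration
#'
#' @param d common pyramid channel width (default 256, the FPN convention)
#' @param attention use the learned fusion weights (`FALSE` leaves plain FPN)
#' @param attention_channels 1 for a single spatial weight map broadcast
#'   across channels (default), or `d` for per-channel weights
#' @param hidden generator hidden width between its 1x1 and 3x3 convolutions
#'   (default `max(4, d/4)`)
#' @param literal_subsample_variant if `TRUE`, laterals come from C2--C4
#'   only and both P5 and P6 are obtained by successive stride-2 subsampling
#'   of the level below (the alternative reading of "twice subsampling");
#'   default `FALSE` uses laterals C2--C5 with P6 subsampled from P5
#' @return list of class `neck_config`
#' @export
neck_config <- function(d = 256L, attention = TRUE, attention_channels = 1L,
                        hidden = NULL, literal_subsample_variant = FALSE) {
  if (is.null(hidden)) hidden <- max(4L, d %/% 4L)
  stopifnot(attention_channels %in% c(1L, d))
  structure(list(d = as.integer(d), attention = attention,
                 attention_channels = as.integer(attention_channels),
                 hidden = as.integer(hidden),
                 literal_subsample_variant = literal_subsample_variant),
            class = "neck_config")
}

weight_generator <- function(cin, hidden, cout, name) {
  list(c1 = conv_layer(cin, hidden, k = 1, name = paste0(name, ".c1")),
       c3 = conv_layer(hidden, cout, k = 3, name = paste0(name, ".c3")))
}

#' Project a backbone stage to the pyramid width with a 1x1 convolution
#'
#' @param Ci `feature_map` or (H, W, C) array
#' @param proj list with `w` ((1, 1, C, d) array) and optional `b`
#' @return (H, W, d) array; spatial size unchanged
#' @export
lateral_project <- function(Ci, proj) {
  v <- fm_values(Ci)
  w <- if (is_td(proj$w)) proj$w$v else proj$w
  b <- if (is_td(proj$b)) proj$b$v else proj$b
  if (dim(w)[1] != 1 || dim(w)[2] != 1) stop("lateral projection must be 1x1")
  if (dim(w)[3] != dim(v)[3]) {
    stop("channel mismatch: projection expects ", dim(w)[3], ", got ",
         dim(v)[3])
  }
  cpp_conv2d_fwd(v, w, if (is.null(b)) numeric(0) else b, 1L, 0L, 1L)
}

#' Nearest-neighbour 2x upsampling
#'
#' Every pixel is replicated into a 2x2 block; the stride halves.
#'
#' @param P `feature_map` or (H, W, C) array
#' @return upsampled array (or `feature_map` when given one)
#' @export
upsample2x_nearest <- function(P) {
  if (inherits(P, "feature_map")) {
    feature_map(cpp_upsample2_fwd(P$values), max(1L, P$stride %/% 2L))
  } else {
    cpp_upsample2_fwd(P)
  }
}

#' Attention weight map for feature fusion
#'
#' `sigmoid(conv3x3(relu(conv1x1(x))))` applied to the upsampled upper
#' pathway; every output value is strictly inside (0, 1).
#'
#' @param upsampled (H, W, d) array (the upsampled upper level)
#' @param gen generator parameters from the neck (two conv layers)
#' @return (H, W, 1) (or (H, W, d)) weight map
#' @export
attention_weights <- function(upsampled, gen) {
  v <- fm_values(upsampled)
  tape <- td_tape()
  out <- attention_weights_t(tape, td_const(v), gen)
  out$v
}

attention_weights_t <- function(tape, x, gen) {
  h <- op_relu(tape, apply_conv(tape, gen$c1, x))
  op_sigmoid(tape, apply_conv(tape, gen$c3, h))
}

#' Fuse one pyramid level
#'
#' `lateral + alpha * upsample2x_nearest(upper)`: the upper level is
#' upsampled, weighted by the fusion map `alpha`, and added to the lateral.
#' With `alpha = 1` everywhere this is exactly the plain-FPN sum.
#'
#' @param lateral (H, W, d) array
#' @param upper (H/2, W/2, d) array (pre-upsampling)
#' @param alpha fusion weight map, (H, W, 1) or (H, W, d), or a scalar
#' @return fused (H, W, d) array
#' @export
fuse_level <- function(lateral, upper, alpha = 1) {
  lat <- fm_values(lateral)
  upv <- fm_values(upper)
  du <- dim(upv)
  dl <- dim(lat)
  # lateral may be one pixel short of 2x upper (odd input sizes)
  if (dl[3] != du[3] || dl[1] > 2 * du[1] || dl[1] < 2 * du[1] - 1 ||
      dl[2] > 2 * du[2] || dl[2] < 2 * du[2] - 1) {
    stop("shape mismatch between lateral (", paste(dl, collapse = "x"),
         ") and upper level (", paste(du, collapse = "x"), ")")
  }
  up <- cpp_upsample2_fwd(upv)
  up <- up[seq_len(dl[1]), seq_len(dl[2]), , drop = FALSE]
  if (length(alpha) == 1) {
    lat + alpha * up
  } else {
    a <- fm_values(alpha)
    lat + array(a, dim = dim(lat)) * up
  }
}

#' Build the fusion-pyramid parameters
#'
#' @param in_channels named channel counts of the backbone stages C2--C5
#' @param cfg a [neck_config()]
#' @return object of class `pd_neck`
#' @export
build_neck <- function(in_channels, cfg = neck_config()) {
  lit <- cfg$literal_subsample_variant
  lat_names <- if (lit) c("C2", "C3", "C4") else c("C2", "C3", "C4", "C5")
  laterals <- lapply(lat_names, function(nm) {
    conv_layer(in_channels[[nm]], cfg$d, k = 1, pad = 0,
               name = paste0("lat.", nm))
  })
  names(laterals) <- lat_names
  fuse_names <- if (lit) c("P2", "P3") else c("P2", "P3", "P4")
  gens <- if (cfg$attention) {
    g <- lapply(fuse_names, function(nm) {
      weight_generator(cfg$d, cfg$hidden, cfg$attention_channels,
                       paste0("wg.", nm))
    })
    names(g) <- fuse_names
    g
  } else NULL
  smooth_names <- if (lit) c("P2", "P3", "P4") else c("P2", "P3", "P4", "P5")
  smooth <- lapply(smooth_names, function(nm) {
    conv_layer(cfg$d, cfg$d, k = 3, name = paste0("smooth.", nm))
  })
  names(smooth) <- smooth_names
  structure(list(laterals = laterals, gens = gens, smooth = smooth,
                 cfg = cfg),
            class = "pd_neck")
}

# tape version; feats: named list of tensors C2..C5; returns list(P = levels,
# alpha = recorded maps). `bypass` forces alpha == 1 (exact FPN).
forward_neck_t <- function(tape, neck, feats, bypass = FALSE) {
  cfg <- neck$cfg
  lit <- cfg$literal_subsample_variant
  lat_names <- names(neck$laterals)
  lats <- lapply(lat_names, function(nm) {
    op_conv2d(tape, feats[[nm]], neck$laterals[[nm]]$w,
              neck$laterals[[nm]]$b, stride = 1, pad = 0)
  })
  names(lats) <- lat_names
  top <- if (lit) "C4" else "C5"
  order_down <- rev(lat_names)
  P <- list()
  alphas <- list()
  cur <- lats[[top]]
  P[[sub("C", "P", top)]] <- cur
  for (nm in order_down[-1]) {
    pname <- sub("C", "P", nm)
    up <- op_upsample2(tape, cur)
    ld <- dim(lats[[nm]]$v)
    if (!identical(dim(up$v)[1:2], ld[1:2])) {
      up <- op_crop(tape, up, ld[1], ld[2])
    }
    if (cfg$attention && !bypass) {
      alpha <- attention_weights_t(tape, up, neck$gens[[pname]])
      alphas[[pname]] <- alpha
      term <- if (cfg$attention_channels == 1L) {
        op_scale_spatial(tape, up, alpha)
      } else {
        op_mul(tape, up, alpha)
      }
    } else {
      term <- up
    }
    cur <- op_add(tape, lats[[nm]], term)
    P[[pname]] <- cur
  }
  out <- list()
  for (nm in names(neck$smooth)) {
    out[[nm]] <- op_conv2d(tape, P[[nm]], neck$smooth[[nm]]$w,
                           neck$smooth[[nm]]$b, stride = 1, pad = 1)
  }
  if (lit) {
    out$P5 <- op_maxpool2(tape, out$P4)
    out$P6 <- op_maxpool2(tape, out$P5)
  } else {
    out$P6 <- op_maxpool2(tape, out$P5)
  }
  out <- out[c("P2", "P3", "P4", "P5", "P6")]
  list(P = out, alpha = alphas)
}

op_crop <- function(tape, x, h, w) {
  td_node(x$v[seq_len(h), seq_len(w), , drop = FALSE], tape,
          bw = function(g) {
            gx <- array(0, dim = dim(x$v))
            gx[seq_len(h), seq_len(w), ] <- g
            acc_grad(x, gx)
          })
}

op_mul <- function(tape, x, y) {
  td_node(x$v * y$v, tape, bw = function(g) {
    acc_grad(x, g * y$v)
    acc_grad(y, g * x$v)
  })
}

#' Build the fused feature pyramid P2--P6
#'
#' Laterals are 1x1-projected backbone stages; each top-down fusion weights
#' the upsampled upper level by its attention map before addition; every
#' fused level passes a final 3x3 smoothing convolution (removing the
#' aliasing of nearest upsampling); P6 comes from stride-2 max subsampling
#' of P5. The attention maps actually used are returned for inspection.
#'
#' @param stage_feats named list of `feature_map`s C2--C5 (strides 4--32)
#' @param neck a `pd_neck` from [build_neck()]
#' @param bypass force `alpha = 1` everywhere (exact plain-FPN behaviour)
#' @return list of class `pyramid_features`: `levels` (named `feature_map`s
#'   P2--P6 at strides 4--64... P6 stride 64 for a stride-32 C5) and
#'   `alpha_maps`
#' @export
build_pyramid <- function(stage_feats, neck, bypass = FALSE) {
  if (!setequal(names(stage_feats), c("C2", "C3", "C4", "C5"))) {
    stop("need exactly stages C2, C3, C4, C5; got ",
         paste(names(stage_feats), collapse = ", "))
  }
  tape <- td_tape()
  feats <- lapply(stage_feats, function(f) td_const(fm_values(f)))
  res <- forward_neck_t(tape, neck, feats, bypass = bypass)
  s5 <- if (inherits(stage_feats$C5, "feature_map"))
    stage_feats$C5$stride else 32L
  strides <- c(P2 = s5 %/% 8L, P3 = s5 %/% 4L, P4 = s5 %/% 2L, P5 = s5,
               P6 = s5 * 2L)
  levels <- mapply(function(t, nm) feature_map(t$v, strides[[nm]]),
                   res$P, names(res$P), SIMPLIFY = FALSE)
  structure(list(levels = levels,
                 alpha_maps = lapply(res$alpha, function(a) a$v)),
            class = "pyramid_features")
}
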