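#' @useDynLib pestdetectr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode autodiff over dense arrays.
#
# Feature maps are (H, W, C) arrays; the tape records every op in creation
# order, so walking it backwards is a valid reverse topological order.
# Parameters (`td_param`) live outside any tape and keep accumulating
# gradients until `zero_grads()`.
# ---------------------------------------------------------------------------

td_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

td_node <- function(value, tape = NULL, parents = NULL, bw = NULL) {
  t <- new.env(parent = emptyenv())
  t$v <- value
  t$g <- NULL
  t$parents <- parents
  t$bw <- bw
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- t
  }
  class(t) <- "td_tensor"
  t
}

#' Create a trainable parameter tensor
#'
#' Parameters are not bound to a tape; their gradients accumulate across all
#' backward passes until [zero_grads()] is called.
#'
#' @param value numeric array of initial values
#' @param name optional identifier used in checkpoints and diagnostics
#' @return a `td_tensor` environment with fields `v` (value) and `g` (gradient)
#' @keywords internal
td_param <- function(value, name = NULL) {
  t <- td_node(value)
  t$param <- TRUE
  t$name <- name
  t
}

td_const <- function(value) td_node(value)

is_td <- function(x) inherits(x, "td_tensor")

acc_grad <- function(t, g) {
  if (is.null(t$g)) t$g <- g else t$g <- t$g + g
  invisible(NULL)
}

#' Run the backward pass from a scalar loss
#'
#' @param loss scalar `td_tensor` produced on `tape`
#' @param tape the tape the forward pass was recorded on
#' @keywords internal
td_backward <- function(loss, tape) {
  loss$g <- 1
  if (tape$n == 0L) return(invisible(NULL))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd$g)
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# -- primitive ops -----------------------------------------------------------

wrap2 <- function(x) if (is_td(x)) x else td_const(x)

op_conv2d <- function(tape, x, w, b, stride = 1L, pad = 0L, dil = 1L) {
  y <- cpp_conv2d_fwd(x$v, w$v, if (is.null(b)) numeric(0) else b$v,
                      as.integer(stride), as.integer(pad), as.integer(dil))
  td_node(y, tape, bw = function(g) {
    gr <- cpp_conv2d_bwd(x$v, w$v, g, as.integer(stride), as.integer(pad),
                         as.integer(dil))
    acc_grad(x, gr$gx)
    acc_grad(w, gr$gw)
    if (!is.null(b)) acc_grad(b, gr$gb)
  })
}

op_deform_conv <- function(tape, x, w, b, off, stride = 1L, pad = 0L,
                           dil = 1L) {
  y <- cpp_deform_fwd(x$v, w$v, if (is.null(b)) numeric(0) else b$v, off$v,
                      as.integer(stride), as.integer(pad), as.integer(dil))
  td_node(y, tape, bw = function(g) {
    gr <- cpp_deform_bwd(x$v, w$v, off$v, g, as.integer(stride),
                         as.integer(pad), as.integer(dil))
    acc_grad(x, gr$gx)
    acc_grad(w, gr$gw)
    if (!is.null(b)) acc_grad(b, gr$gb)
    acc_grad(off, gr$goff)
  })
}

op_relu <- function(tape, x) {
  mask <- x$v > 0
  td_node(x$v * mask, tape, bw = function(g) acc_grad(x, g * mask))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$v))
  td_node(s, tape, bw = function(g) acc_grad(x, g * s * (1 - s)))
}

op_add <- function(tape, x, y) {
  td_node(x$v + y$v, tape, bw = function(g) {
    acc_grad(x, g)
    acc_grad(y, g)
  })
}

# x: (H, W, C); alpha: (H, W, 1) broadcast across channels
op_scale_spatial <- function(tape, x, alpha) {
  C <- dim(x$v)[3]
  a3 <- array(alpha$v, dim = dim(x$v))
  td_node(x$v * a3, tape, bw = function(g) {
    acc_grad(x, g * a3)
    ga <- apply(g * x$v, c(1, 2), sum)
    acc_grad(alpha, array(ga, dim = dim(alpha$v)))
  })
}

op_upsample2 <- function(tape, x) {
  td_node(cpp_upsample2_fwd(x$v), tape,
          bw = function(g) acc_grad(x, cpp_upsample2_bwd(g)))
}

op_maxpool2 <- function(tape, x) {
  fw <- cpp_maxpool2_fwd(x$v)
  xd <- dim(x$v)
  td_node(fw$y, tape,
          bw = function(g) acc_grad(x, cpp_maxpool2_bwd(g, fw$idx,
                                                        as.integer(xd))))
}

# rois: plain n x 4 matrix in feature coordinates (r1, c1, r2, c2)
op_roialign <- function(tape, feat, rois, ph, pw, nsamp = 2L) {
  fd <- dim(feat$v)
  y <- cpp_roialign_fwd(feat$v, rois, as.integer(ph), as.integer(pw),
                        as.integer(nsamp))
  td_node(y, tape, bw = function(g) {
    acc_grad(feat, cpp_roialign_bwd(g, rois, as.integer(fd), as.integer(ph),
                                    as.integer(pw), as.integer(nsamp)))
  })
}

# (ph, pw, C, n) -> n x (ph*pw*C) matrix
op_flatten_rois <- function(tape, x) {
  d <- dim(x$v)
  n <- d[4]
  m <- matrix(x$v, nrow = prod(d[1:3]), ncol = n)
  td_node(t(m), tape, bw = function(g) {
    acc_grad(x, array(t(g), dim = d))
  })
}

op_linear <- function(tape, x, w, b = NULL) {
  y <- x$v %*% w$v
  if (!is.null(b)) y <- sweep(y, 2, b$v, "+")
  td_node(y, tape, bw = function(g) {
    acc_grad(x, g %*% t(w$v))
    acc_grad(w, crossprod(x$v, g))
    if (!is.null(b)) acc_grad(b, colSums(g))
  })
}

# Gather a set of unique linear indices out of an array into a vector.
op_gather <- function(tape, x, idx) {
  stopifnot(!anyDuplicated(idx))
  xd <- dim(x$v)
  td_node(x$v[idx], tape, bw = function(g) {
    gx <- array(0, dim = xd)
    gx[idx] <- g
    acc_grad(x, gx)
  })
}

op_concat <- function(tape, xs) {
  lens <- vapply(xs, function(t) length(t$v), 1L)
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  td_node(unlist(lapply(xs, function(t) as.vector(t$v))), tape,
          bw = function(g) {
            for (i in seq_along(xs)) {
              acc_grad(xs[[i]], array(g[starts[i]:ends[i]],
                                      dim = dim(xs[[i]]$v) %||% lens[i]))
            }
          })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- losses ------------------------------------------------------------------

# mean binary cross-entropy on logits; targets in {0,1}
op_bce_logits <- function(tape, logits, targets) {
  z <- logits$v
  n <- length(z)
  # stable: log(1+exp(-|z|)) + max(z,0) - z*t
  l <- mean(pmax(z, 0) - z * targets + log1p(exp(-abs(z))))
  p <- 1 / (1 + exp(-z))
  td_node(l, tape, bw = function(g) acc_grad(logits, g * (p - targets) / n))
}

# mean softmax cross-entropy; logits n x k, target integer class in 1..k
op_softmax_ce <- function(tape, logits, target) {
  z <- logits$v
  n <- nrow(z)
  zm <- z - apply(z, 1, max)
  ez <- exp(zm)
  p <- ez / rowSums(ez)
  l <- -mean(log(pmax(p[cbind(seq_len(n), target)], 1e-12)))
  td_node(l, tape, bw = function(g) {
    gp <- p
    gp[cbind(seq_len(n), target)] <- gp[cbind(seq_len(n), target)] - 1
    acc_grad(logits, g * gp / n)
  })
}

# smooth L1 (Huber) summed over elements, divided by `norm`
op_smooth_l1 <- function(tape, pred, target, beta = 1 / 9, norm = 1) {
  d <- pred$v - target
  a <- abs(d)
  l <- sum(ifelse(a < beta, 0.5 * d^2 / beta, a - 0.5 * beta)) / norm
  td_node(l, tape, bw = function(g) {
    gd <- ifelse(a < beta, d / beta, sign(d)) / norm
    acc_grad(pred, g * gd)
  })
}

# weighted sum of scalar tensors
op_wsum <- function(tape, xs, ws = rep(1, length(xs))) {
  v <- sum(vapply(seq_along(xs), function(i) ws[i] * xs[[i]]$v, 0))
  td_node(v, tape, bw = function(g) {
    for (i in seq_along(xs)) acc_grad(xs[[i]], g * ws[i])
  })
}

# -- optimizer ---------------------------------------------------------------

#' Stochastic gradient descent with momentum and gradient clipping
#'
#' @param params list of `td_param` tensors
#' @param lr learning rate
#' @param momentum momentum coefficient
#' @param clip global gradient-norm ceiling (Inf disables clipping)
#' @param weight_decay L2 penalty coefficient
#' @keywords internal
sgd_new <- function(params, lr = 0.01, momentum = 0.9, clip = 10,
                    weight_decay = 1e-4) {
  list(params = params, lr = lr, momentum = momentum, clip = clip,
       weight_decay = weight_decay,
       buf = lapply(params, function(p) p$v * 0))
}

sgd_step <- function(opt) {
  gn2 <- 0
  for (p in opt$params) if (!is.null(p$g)) gn2 <- gn2 + sum(p$g^2)
  gn <- sqrt(gn2)
  scale <- if (is.finite(opt$clip) && gn > opt$clip) opt$clip / gn else 1
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$g)) next
    g <- p$g * scale + opt$weight_decay * p$v
    opt$buf[[i]] <- opt$momentum * opt$buf[[i]] + g
    p$v <- p$v - opt$lr * opt$buf[[i]]
  }
  zero_grads(opt$params)
  opt
}
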