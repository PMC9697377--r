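# Independent oracles used to cross-check the package's numerical paths.
# These are deliberately written as direct, literal implementations (nested
# loops, full-grid sums, fine-grid integration) and share no code with the
# package internals they check.

# direct 2-D convolution by tap-shifted accumulation on a zero-padded copy
oracle_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dil * (kw - 1) - 1) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, Cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  y <- array(0, c(Ho, Wo, Cout))
  rows <- (seq_len(Ho) - 1) * stride
  cols <- (seq_len(Wo) - 1) * stride
  for (co in seq_len(Cout)) {
    acc <- matrix(if (is.null(b)) 0 else b[co], Ho, Wo)
    for (ci in seq_len(Cin)) {
      for (kj in seq_len(kw)) {
        for (ki in seq_len(kh)) {
          acc <- acc + w[ki, kj, ci, co] *
            xp[rows + 1 + (ki - 1) * dil, cols + 1 + (kj - 1) * dil, ci]
        }
      }
    }
    y[, , co] <- acc
  }
  y
}

# literal tent-kernel sum over every grid point
oracle_bilinear <- function(x, lx, ly, ch = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]
  out <- 0
  for (kx in 0:(W - 1)) {
    for (ky in 0:(H - 1)) {
      g <- max(0, 1 - abs(kx - lx)) * max(0, 1 - abs(ky - ly))
      if (g > 0) out <- out + g * x[ky + 1, kx + 1, ch]
    }
  }
  out
}

# loop-based cumulative precision/recall
oracle_pr <- function(tp, n_gt) {
  prec <- numeric(length(tp)); rec <- numeric(length(tp))
  ctp <- 0
  for (k in seq_along(tp)) {
    if (tp[k]) ctp <- ctp + 1
    prec[k] <- ctp / k
    rec[k] <- ctp / n_gt
  }
  list(precision = prec, recall = rec)
}

# fine-grid Riemann integration of the monotone-envelope PR curve:
# p_env(r) = max precision among curve points with recall >= r
oracle_ap_grid <- function(precision, recall, n_grid = 2e4) {
  if (length(recall) == 0) return(0)
  o <- order(recall)
  rec <- recall[o]; prec <- precision[o]
  # suffix max over increasing recall
  smax <- rev(cummax(rev(prec)))
  r <- (seq_len(n_grid) - 0.5) / n_grid
  pos <- findInterval(r, rec, left.open = TRUE) + 1L  # first point with rec >= r
  p <- ifelse(pos <= length(rec), smax[pmin(pos, length(rec))], 0)
  mean(p)
}

# plain FPN composed from oracle primitives (no attention, alpha = 1)
oracle_fpn <- function(feats, lat_w, lat_b, smooth_w, smooth_b) {
  nms <- c("C2", "C3", "C4", "C5")
  lats <- lapply(nms, function(nm) {
    oracle_conv2d(feats[[nm]], lat_w[[nm]], lat_b[[nm]], pad = 0)
  })
  names(lats) <- nms
  up2 <- function(x) {
    d <- dim(x)
    y <- array(0, c(2 * d[1], 2 * d[2], d[3]))
    for (c in seq_len(d[3])) y[, , c] <- kronecker(x[, , c], matrix(1, 2, 2))
    y
  }
  P <- list(P5 = lats$C5)
  P$P4 <- lats$C4 + up2(P$P5)
  P$P3 <- lats$C3 + up2(P$P4)
  P$P2 <- lats$C2 + up2(P$P3)
  out <- lapply(c("P2", "P3", "P4", "P5"), function(nm) {
    oracle_conv2d(P[[nm]], smooth_w[[nm]], smooth_b[[nm]], pad = 1)
  })
  names(out) <- c("P2", "P3", "P4", "P5")
  # stride-2 max subsampling for the extra top level
  x <- out$P5
  d <- dim(x)
  p6 <- array(0, c(d[1] %/% 2, d[2] %/% 2, d[3]))
  if (all(dim(p6)[1:2] >= 1)) {
    for (c in seq_len(d[3])) {
      for (j in seq_len(d[2] %/% 2)) {
        for (i in seq_len(d[1] %/% 2)) {
          p6[i, j, c] <- max(x[2 * i - 1:0, 2 * j - 1:0, c])
        }
      }
    }
  }
  out$P6 <- p6
  out
}

# central finite-difference gradient of scalar fn at v
numeric_grad <- function(fn, v, eps = 1e-5) {
  g <- numeric(length(v))
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    g[i] <- (fn(vp) - fn(vm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}
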