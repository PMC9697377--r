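# Layer constructors: a layer is a list of td_param tensors plus metadata.
# Initialization is He-style for ReLU stacks; offset-predicting convolutions
# are zero-initialized so a deformable network starts out exactly equal to
# its regular counterpart.

conv_init <- function(kh, kw, cin, cout, init = "he", gain = 1) {
  if (init == "zero") {
    array(0, dim = c(kh, kw, cin, cout))
  } else {
    sd <- gain * sqrt(2 / (kh * kw * cin))
    array(rnorm(kh * kw * cin * cout, 0, sd), dim = c(kh, kw, cin, cout))
  }
}

conv_layer <- function(cin, cout, k = 3, stride = 1, pad = NULL, dil = 1,
                       init = "he", gain = 1, bias = TRUE, name = "conv") {
  if (is.null(pad)) pad <- dil * (k - 1) %/% 2
  list(w = td_param(conv_init(k, k, cin, cout, init, gain),
                    paste0(name, ".w")),
       b = if (bias) td_param(numeric(cout), paste0(name, ".b")) else NULL,
       stride = stride, pad = pad, dil = dil, kind = "conv")
}

# deformable 3x3: main weights + a zero-initialized offset-predicting conv
deform_layer <- function(cin, cout, k = 3, stride = 1, pad = NULL, dil = 1,
                         gain = 1, name = "dconv") {
  if (is.null(pad)) pad <- dil * (k - 1) %/% 2
  list(w = td_param(conv_init(k, k, cin, cout, "he", gain),
                    paste0(name, ".w")),
       b = td_param(numeric(cout), paste0(name, ".b")),
       off = conv_layer(cin, 2 * k * k, k = k, stride = stride, pad = pad,
                        dil = dil, init = "zero",
                        name = paste0(name, ".off")),
       stride = stride, pad = pad, dil = dil, kind = "deform")
}

linear_layer <- function(din, dout, init = "he", name = "fc") {
  sd <- if (init == "zero") 0 else sqrt(2 / din)
  list(w = td_param(matrix(rnorm(din * dout, 0, sd), din, dout),
                    paste0(name, ".w")),
       b = td_param(numeric(dout), paste0(name, ".b")),
       kind = "linear")
}

apply_conv <- function(tape, layer, x) {
  if (layer$kind == "deform") {
    off <- op_conv2d(tape, x, layer$off$w, layer$off$b,
                     stride = layer$stride, pad = layer$off$pad,
                     dil = layer$dil)
    op_deform_conv(tape, x, layer$w, layer$b, off,
                   stride = layer$stride, pad = layer$pad, dil = layer$dil)
  } else {
    op_conv2d(tape, x, layer$w, layer$b, stride = layer$stride,
              pad = layer$pad, dil = layer$dil)
  }
}

apply_linear <- function(tape, layer, x) op_linear(tape, x, layer$w, layer$b)

# recursively collect every td_param in a nested structure
collect_params <- function(x) {
  if (is_td(x)) {
    if (isTRUE(x$param)) return(list(x))
    return(list())
  }
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

n_params <- function(x) sum(vapply(collect_params(x),
                                   function(p) length(p$v), 0))

get_weights <- function(x) lapply(collect_params(x), function(p) p$v)

set_weights <- function(x, ws) {
  ps <- collect_params(x)
  stopifnot(length(ps) == length(ws))
  for (i in seq_along(ps)) {
    stopifnot(length(ps[[i]]$v) == length(ws[[i]]))
    ps[[i]]$v <- ws[[i]]
  }
  invisible(x)
}
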