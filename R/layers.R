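# Layer constructors and parameter bookkeeping for the conv-net. A "layer"
# is a plain list holding ag_param nodes (and, for batch norm, a state
# environment with running statistics); models are nested lists of layers.

he_init <- function(kh, kw, ci, co, gain = 2) {
  sd <- sqrt(gain / (kh * kw * ci))
  array(stats::rnorm(kh * kw * ci * co, 0, sd), c(kh, kw, ci, co))
}

new_conv <- function(kh, kw, ci, co, stride = 1L, pad = (kh - 1L) %/% 2L,
                     bias_init = 0) {
  structure(list(w = ag_param(he_init(kh, kw, ci, co)),
                 b = ag_param(rep(bias_init, co)),
                 stride = as.integer(stride), pad = as.integer(pad)),
            class = "conv_layer")
}

fwd_conv <- function(layer, x) ag_conv2d(x, layer$w, layer$b, layer$stride, layer$pad)

new_bn <- function(c) {
  state <- new.env(parent = emptyenv())
  state$running_mean <- rep(0, c)
  state$running_var <- rep(1, c)
  structure(list(gamma = ag_param(rep(1, c)), beta = ag_param(rep(0, c)),
                 state = state), class = "bn_layer")
}

fwd_bn <- function(layer, x, training) ag_bn2d(x, layer$gamma, layer$beta, layer$state, training)

new_fc <- function(ci, co, bias_init = 0) {
  sd <- sqrt(2 / ci)
  structure(list(w = ag_param(matrix(stats::rnorm(ci * co, 0, sd), co, ci)),
                 b = ag_param(rep(bias_init, co))), class = "fc_layer")
}

fwd_fc <- function(layer, x) ag_fc(x, layer$w, layer$b)

# Squeeze-and-excitation parameters: W1 (c/r x c), W2 (c x c/r), no biases.
new_se <- function(c, r = 16L) {
  if (c %% r != 0) stop("SE reduction ratio r must divide the channel count")
  cr <- c %/% r
  structure(list(W1 = ag_param(matrix(stats::rnorm(cr * c, 0, sqrt(2 / c)), cr, c)),
                 W2 = ag_param(matrix(stats::rnorm(c * cr, 0, sqrt(2 / cr)), c, cr)),
                 r = as.integer(r)), class = "se_layer")
}

new_basic_block <- function(ci, co, stride) {
  structure(list(conv1 = new_conv(3, 3, ci, co, stride),
                 bn1 = new_bn(co),
                 conv2 = new_conv(3, 3, co, co, 1),
                 bn2 = new_bn(co),
                 down = if (stride != 1L || ci != co)
                   list(conv = new_conv(1, 1, ci, co, stride, pad = 0L),
                        bn = new_bn(co))),
            class = "basic_block")
}

fwd_basic_block <- function(bl, x, training) {
  y <- ag_relu(fwd_bn(bl$bn1, fwd_conv(bl$conv1, x), training))
  y <- fwd_bn(bl$bn2, fwd_conv(bl$conv2, y), training)
  sk <- if (is.null(bl$down)) x else fwd_bn(bl$down$bn, fwd_conv(bl$down$conv, x), training)
  ag_relu(ag_add(y, sk))
}

new_bottleneck <- function(ci, w, stride) {
  co <- 4L * w
  structure(list(conv1 = new_conv(1, 1, ci, w, 1, pad = 0L), bn1 = new_bn(w),
                 conv2 = new_conv(3, 3, w, w, stride), bn2 = new_bn(w),
                 conv3 = new_conv(1, 1, w, co, 1, pad = 0L), bn3 = new_bn(co),
                 down = if (stride != 1L || ci != co)
                   list(conv = new_conv(1, 1, ci, co, stride, pad = 0L),
                        bn = new_bn(co))),
            class = "bottleneck_block")
}

fwd_bottleneck <- function(bl, x, training) {
  y <- ag_relu(fwd_bn(bl$bn1, fwd_conv(bl$conv1, x), training))
  y <- ag_relu(fwd_bn(bl$bn2, fwd_conv(bl$conv2, y), training))
  y <- fwd_bn(bl$bn3, fwd_conv(bl$conv3, y), training)
  sk <- if (is.null(bl$down)) x else fwd_bn(bl$down$bn, fwd_conv(bl$down$conv, x), training)
  ag_relu(ag_add(y, sk))
}

# Recursively collect ag_param nodes from a nested layer list.
collect_params <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "agnode")) {
    if (isTRUE(x$is_param)) out[[prefix]] <- x
    return(out)
  }
  if (is.list(x)) {
    nm <- names(x)
    for (i in seq_along(x)) {
      if (is.null(x[[i]])) next
      label <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      out <- c(out, collect_params(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", label)))
    }
  }
  out
}

collect_bn_states <- function(x, prefix = "") {
  out <- list()
  if (inherits(x, "bn_layer")) {
    out[[prefix]] <- x$state
  }
  if (is.list(x)) {
    nm <- names(x)
    for (i in seq_along(x)) {
      if (is.null(x[[i]])) next
      label <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
      out <- c(out, collect_bn_states(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", label)))
    }
  }
  out
}

model_state <- function(model) {
  list(params = lapply(collect_params(model), function(p) p$val),
       bn = lapply(collect_bn_states(model), function(s)
         list(mean = s$running_mean, var = s$running_var)))
}

load_model_state <- function(model, state) {
  ps <- collect_params(model)
  for (nm in names(state$params)) {
    if (is.null(ps[[nm]])) stop("unknown parameter in checkpoint: ", nm)
    stopifnot(length(ps[[nm]]$val) == length(state$params[[nm]]))
    v <- state$params[[nm]]
    dim(v) <- dim(ps[[nm]]$val)
    ps[[nm]]$val <- v
  }
  bs <- collect_bn_states(model)
  for (nm in names(state$bn)) {
    bs[[nm]]$running_mean <- state$bn[[nm]]$mean
    bs[[nm]]$running_var <- state$bn[[nm]]$var
  }
  invisible(model)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

global_grad_norm <- function(params) {
  sq <- 0
  for (p in params) if (!is.null(p$grad)) sq <- sq + sum(p$grad^2)
  sqrt(sq)
}

# SGD with momentum, weight decay and global-norm gradient clipping.
# Returns the post-clip gradient norm actually applied.
sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 1e-4,
                     clip_norm = 1.0) {
  gn <- global_grad_norm(params)
  scale <- if (is.finite(clip_norm) && gn > clip_norm) clip_norm / (gn + 1e-12) else 1
  for (p in params) {
    g <- if (is.null(p$grad)) 0 * p$val else p$grad * scale
    g <- g + weight_decay * p$val
    p$mom <- if (is.null(p$mom)) g else momentum * p$mom + g
    p$val <- p$val - lr * p$mom
  }
  min(gn, clip_norm)
}
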