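#' @useDynLib dcnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- tensor helpers --------------------------------------------------------

#' Construct a (H, W, C, N) tensor from a 2-d image or a list of images
#'
#' Feature tensors throughout the package are dense double arrays with
#' dimensions height x width x channels x batch.
#'
#' @param x a matrix, a 3-d array (H, W, C), or a list of matrices.
#' @return a 4-d array.
#' @export
as_tensor <- function(x) {
  if (is.list(x)) {
    stopifnot(length(x) >= 1L)
    d <- dim(x[[1]])
    out <- array(0, c(d[1], d[2], 1L, length(x)))
    for (i in seq_along(x)) out[, , 1L, i] <- x[[i]]
    return(out)
  }
  d <- dim(x)
  if (is.null(d)) stop("cannot make a tensor from a dimensionless object")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

#' Convert a tensor to an ordinary double array
#'
#' Feature tensors may be carried in single precision (class
#' `dcnet_ft32`); this converts either representation to a plain double
#' array for inspection.
#'
#' @param x a tensor.
#' @return a double array with the same dimensions.
#' @export
as_array <- function(x) {
  if (is.integer(x)) cpp_to_f64(x) else x
}

is_ft32 <- function(x) is.integer(x)

# Zero tensor with the given dims in the given precision.
zeros_tensor <- function(d, single = FALSE) {
  if (single) structure(array(0L, d), class = "dcnet_ft32")
  else array(0, d)
}

zeros_like <- function(x) zeros_tensor(dim(x), is_ft32(x))

tensor_channels <- function(x) dim(x)[3]

# ---- leaf modules ----------------------------------------------------------
# Modules are environments so that parameter updates and cached activations
# mutate in place.  Each leaf carries: params (named list of arrays), grads,
# momentum buffers, a `group` tag ("encoder"/"decoder") used by freeze(),
# and a cache used between forward and backward.

new_module <- function(type, group = "encoder", name = type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$group <- group
  m$name <- name
  m$frozen <- FALSE
  class(m) <- c(paste0("dcnet_", type), "dcnet_module")
  m
}

#' @keywords internal
new_conv <- function(kh, kw, cin, cout, dilation = 1L, bias = TRUE,
                     group = "encoder", name = "conv", gain = 2) {
  m <- new_module("conv", group, name)
  fan_in <- kh * kw * cin
  m$w <- array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(gain / fan_in)),
               c(kh, kw, cin, cout))
  m$b <- if (bias) numeric(cout) else numeric(0)
  m$dilation <- as.integer(dilation)
  m$param_names <- if (bias) c("w", "b") else "w"
  m$gw <- zeros_like(m$w)
  m$gb <- numeric(length(m$b))
  m
}

conv_fwd <- function(m, x) {
  m$x <- x
  cpp_conv_fwd(x, m$w, m$b, m$dilation)
}

# daccum: optional wider gradient buffer to accumulate dx into (in place).
conv_bwd <- function(m, dy, want_dx = TRUE, daccum = NULL) {
  want_dw <- !isTRUE(m$frozen)
  r <- cpp_conv_bwd(m$x, m$w, dy, m$dilation, want_dx, daccum, want_dw)
  if (want_dw) {
    m$gw <- m$gw + r$dw
    if (length(m$b)) m$gb <- m$gb + r$db
  }
  m$x <- NULL
  if (want_dx && is.null(daccum)) r$dx else invisible(NULL)
}

#' @keywords internal
new_bnrelu <- function(c, group = "encoder", name = "bn",
                       momentum = 0.1, eps = 1e-5) {
  m <- new_module("bnrelu", group, name)
  m$gamma <- rep(1, c)
  m$beta <- numeric(c)
  m$rmean <- numeric(c)
  m$rvar <- rep(1, c)
  m$momentum <- momentum
  m$eps <- eps
  m$param_names <- c("gamma", "beta")
  m$ggamma <- numeric(c)
  m$gbeta <- numeric(c)
  m
}

# `cin` may be smaller than the channel count of x (dense-block buffers).
bn_fwd <- function(m, x, training = FALSE, cin = length(m$gamma),
                   stats = NULL) {
  r <- cpp_bn_relu_fwd(x, cin, m$gamma, m$beta, m$rmean, m$rvar,
                       training, m$momentum, m$eps, stats)
  if (training) {
    m$rmean <- r$rmean
    m$rvar <- r$rvar
  }
  m$x <- x
  m$y <- r$y
  m$mean <- r$mean
  m$invstd <- r$invstd
  m$training <- training
  r$y
}

# Accumulates dx into the first `cin` channels of daccum (in place).
bn_bwd <- function(m, dy, daccum, cin = length(m$gamma)) {
  r <- cpp_bn_relu_bwd(m$x, cin, m$gamma, dy, m$y, m$mean, m$invstd,
                       daccum, m$training)
  m$ggamma <- m$ggamma + r$dgamma
  m$gbeta <- m$gbeta + r$dbeta
  m$x <- NULL
  m$y <- NULL
  invisible(NULL)
}

# Dropout with inverted scaling; returns list(y, mask).  RNG comes from the
# R session so fixed seeds reproduce runs bit for bit.
dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  list(y = x, mask = cpp_dropout_fwd(x, rate))
}

dropout_bwd <- function(dy, mask, rate) {
  if (!is.null(mask)) cpp_dropout_bwd(dy, mask, rate)
  dy
}

grad_names <- function(m) {
  c(w = "gw", b = "gb", gamma = "ggamma", beta = "gbeta")[m$param_names]
}

# ---- module collections ----------------------------------------------------

#' Number of trainable parameters of a network
#'
#' Sums the element counts of all trainable tensors (convolution weights and
#' biases, batch-normalization scales and shifts).  Running batch statistics
#' are buffers, not parameters, and are not counted.  Modules marked frozen
#' (see [freeze()]) are excluded when `trainable_only = TRUE`.
#'
#' @param net a network built with [dcnet_network()], or a list of modules.
#' @param trainable_only exclude frozen modules (default `TRUE`).
#' @return integer parameter count.
#' @export
count_parameters <- function(net, trainable_only = TRUE) {
  mods <- module_list(net)
  tot <- 0L
  for (m in mods) {
    if (trainable_only && isTRUE(m$frozen)) next
    for (p in m$param_names) tot <- tot + length(m[[p]])
  }
  tot
}

#' Flat list of the leaf modules of a network
#' @param net a network or a (possibly nested) list of modules.
#' @return named list of leaf module environments.
#' @export
module_list <- function(net) {
  if (inherits(net, "dcnet_module")) return(stats::setNames(list(net), net$name))
  if (inherits(net, "dcnet")) return(net$modules)
  if (is.list(net)) {
    out <- list()
    for (el in net) out <- c(out, module_list(el))
    return(out)
  }
  stop("not a module or network")
}

zero_grads <- function(net) {
  for (m in module_list(net)) {
    for (g in grad_names(m)) m[[g]] <- m[[g]] * 0
  }
  invisible(net)
}

#' Extract (copies of) all parameters of a network
#' @param net a network.
#' @return named list of parameter arrays, suitable for [load_state()].
#' @export
get_state <- function(net) {
  out <- list()
  for (m in module_list(net)) {
    for (p in m$param_names) out[[paste0(m$name, ".", p)]] <- m[[p]]
    if (m$type == "bnrelu") {
      out[[paste0(m$name, ".rmean")]] <- m$rmean
      out[[paste0(m$name, ".rvar")]] <- m$rvar
    }
  }
  out
}

#' Load parameters previously extracted with [get_state()]
#' @param net a network with identical architecture.
#' @param state named list from [get_state()].
#' @export
load_state <- function(net, state) {
  for (m in module_list(net)) {
    for (p in m$param_names) {
      key <- paste0(m$name, ".", p)
      if (is.null(state[[key]])) stop("state is missing ", key)
      m[[p]] <- state[[key]]
    }
    if (m$type == "bnrelu") {
      m$rmean <- state[[paste0(m$name, ".rmean")]]
      m$rvar <- state[[paste0(m$name, ".rvar")]]
    }
  }
  invisible(net)
}

# SGD with classical momentum and optional global gradient-norm clipping;
# skips frozen modules.
sgd_step <- function(net, lr, momentum = 0.9, clip_norm = Inf) {
  scale <- 1
  if (is.finite(clip_norm)) {
    ss <- 0
    for (m in module_list(net)) {
      if (isTRUE(m$frozen)) next
      for (g in grad_names(m)) ss <- ss + sum(m[[g]]^2)
    }
    gnorm <- sqrt(ss)
    if (gnorm > clip_norm) scale <- clip_norm / gnorm
  }
  for (m in module_list(net)) {
    if (isTRUE(m$frozen)) next
    gn <- grad_names(m)
    for (i in seq_along(m$param_names)) {
      p <- m$param_names[i]
      g <- m[[gn[i]]] * scale
      vkey <- paste0("v_", p)
      v <- if (is.null(m[[vkey]])) g * 0 else m[[vkey]]
      v <- momentum * v + g
      m[[vkey]] <- v
      m[[p]] <- m[[p]] - lr * v
    }
  }
  invisible(net)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
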