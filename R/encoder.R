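# Encoder: dense blocks with dilated bottleneck layers, channel-compressing
# transitions, 2x2 average pooling after the first two blocks, and a
# PSPNet-style pyramid pooling module on the deepest feature map.

# ---- dense layer -----------------------------------------------------------

#' Create a standalone dense layer
#'
#' One dense layer maps its (concatenated) input to `growth` new channels
#' at unchanged spatial size: BN+ReLU+Conv1x1 to a narrow bottleneck,
#' then BN+ReLU+dilated Conv3x3 with zero "same" padding.  The bottleneck
#' keeps the layer's cost linear in its input width, which is what puts
#' the full network inside its 0.28 M parameter budget.
#'
#' @param cin input channels.
#' @param growth output channels.
#' @param bottleneck bottleneck width of the 1x1 convolution.
#' @param dilation dilation factor of the 3x3 convolution.
#' @param drop_rate dropout rate applied after each convolution when
#'   training.
#' @param group freeze group tag.
#' @param name module name prefix.
#' @return a dense-layer container.
#' @export
new_dense_layer <- function(cin, growth, bottleneck = 7L, dilation = 1L,
                            drop_rate = 0, group = "encoder",
                            name = "dense_layer") {
  lay <- new.env(parent = emptyenv())
  lay$bn1 <- new_bnrelu(cin, group, paste0(name, ".bn1"))
  lay$conv1 <- new_conv(1L, 1L, cin, bottleneck, group = group,
                        name = paste0(name, ".conv1"))
  lay$bn2 <- new_bnrelu(bottleneck, group, paste0(name, ".bn2"))
  lay$conv2 <- new_conv(3L, 3L, bottleneck, growth, dilation = dilation,
                        group = group, name = paste0(name, ".conv2"))
  lay$cin <- as.integer(cin)
  lay$growth <- as.integer(growth)
  lay$drop_rate <- drop_rate
  class(lay) <- c("dcnet_dense_layer", "dcnet_module_group")
  lay
}

#' Forward pass of a standalone dense layer
#'
#' @param layer a layer from [new_dense_layer()].
#' @param x input tensor with `layer$cin` channels (a wider buffer is
#'   allowed; only the first `layer$cin` channels are read).
#' @param training use batch statistics and dropout.
#' @return a tensor with `layer$growth` channels and the input's spatial
#'   size.
#' @export
dense_layer_forward <- function(layer, x, training = FALSE, stats = NULL) {
  x <- as_tensor(x)
  a <- bn_fwd(layer$bn1, x, training, cin = layer$cin, stats = stats)
  h <- conv_fwd(layer$conv1, a)
  d1 <- dropout_fwd(h, layer$drop_rate, training)
  layer$mask1 <- d1$mask
  layer$h1dim <- dim(h)
  a2 <- bn_fwd(layer$bn2, d1$y, training)
  o <- conv_fwd(layer$conv2, a2)
  d2 <- dropout_fwd(o, layer$drop_rate, training)
  layer$mask2 <- d2$mask
  layer$ft <- is_ft32(x)
  d2$y
}

# Backward: accumulates the input gradient into the first `cin` channels of
# `daccum` (in place) and parameter gradients into the layer's modules.
dense_layer_backward <- function(layer, dy, daccum) {
  dy <- dropout_bwd(dy, layer$mask2, layer$drop_rate)
  da2 <- conv_bwd(layer$conv2, dy)
  dh <- zeros_tensor(layer$h1dim, layer$ft)
  bn_bwd(layer$bn2, da2, dh)
  dh <- dropout_bwd(dh, layer$mask1, layer$drop_rate)
  da <- conv_bwd(layer$conv1, dh)
  bn_bwd(layer$bn1, da, daccum, cin = layer$cin)
  invisible(NULL)
}

# ---- dense block -----------------------------------------------------------

new_block <- function(cfg, b, cin, name) {
  blk <- new.env(parent = emptyenv())
  blk$c0 <- as.integer(cin)
  blk$dense <- cfg$use_dense_connections
  blk$L <- cfg$layers_per_block
  blk$g <- cfg$growth_rate
  blk$layers <- vector("list", blk$L)
  for (k in seq_len(blk$L)) {
    if (blk$dense) {
      lcin <- cin + (k - 1L) * cfg$growth_rate
      lout <- cfg$growth_rate
    } else {
      # sequential ablation: constant width, last layer widened so the block
      # emits the same channel count as the reference block-plus-transition
      lcin <- if (k == 1L) cin else cfg$growth_rate
      lout <- if (k == blk$L) cfg$transition_out_channels[b] else cfg$growth_rate
    }
    blk$layers[[k]] <- new_dense_layer(lcin, lout, cfg$bottleneck_channels,
                                       cfg$dilation_schedule[b],
                                       cfg$drop_rate, "encoder",
                                       sprintf("%s.l%02d", name, k))
  }
  blk$cout <- if (blk$dense) cin + blk$L * blk$g
              else cfg$transition_out_channels[b]
  blk
}

#' Forward pass of one dense block
#'
#' With dense connections the block output is the channel concatenation of
#' the block input with every layer's output
#' (`cin + layers_per_block * growth_rate` channels); without them the
#' layers run sequentially.  Spatial size never changes inside a block.
#'
#' @param net a network from [dcnet_network()].
#' @param block block index.
#' @param x input tensor.
#' @param training training mode.
#' @return the block output (pre-transition).
#' @export
dense_block_forward <- function(net, block, x, training = FALSE) {
  blk <- net$blocks[[block]]
  x <- as_tensor(x)
  d <- dim(x)
  if (d[3] != blk$c0)
    stop(sprintf("block %d expects %d channels, got %d", block, blk$c0, d[3]))
  if (!blk$dense) {
    h <- x
    for (k in seq_len(blk$L))
      h <- dense_layer_forward(blk$layers[[k]], h, training)
    return(h)
  }
  buf <- zeros_tensor(c(d[1], d[2], blk$c0 + blk$L * blk$g, d[4]), is_ft32(x))
  cpp_write_channels(buf, x, 0L)
  # the batch statistics of a buffer channel are identical for every layer
  # that reads it, so they are computed once and shared across the
  # per-layer batch-norm modules
  stats <- if (training) cpp_channel_stats(buf, 0L, blk$c0) else NULL
  for (k in seq_len(blk$L)) {
    o <- dense_layer_forward(blk$layers[[k]], buf, training, stats = stats)
    off <- blk$c0 + (k - 1L) * blk$g
    cpp_write_channels(buf, o, off)
    if (training) {
      ns <- cpp_channel_stats(buf, off, blk$g)
      stats <- list(mean = c(stats$mean, ns$mean),
                    var = c(stats$var, ns$var))
    }
  }
  blk$stats <- if (training) stats else NULL
  buf
}

# dbuf is the gradient of the full concatenated block output; returns the
# gradient with respect to the block input.
dense_block_backward <- function(net, block, dbuf) {
  blk <- net$blocks[[block]]
  if (!blk$dense) {
    dy <- dbuf
    for (k in rev(seq_len(blk$L))) {
      lay <- blk$layers[[k]]
      dx <- zeros_tensor(c(dim(dy)[1], dim(dy)[2], lay$cin, dim(dy)[4]),
                         is_ft32(dy))
      dense_layer_backward(lay, dy, dx)
      dy <- dx
    }
    return(dy)
  }
  for (k in rev(seq_len(blk$L))) {
    off <- blk$c0 + (k - 1L) * blk$g
    dy <- cpp_slice_channels(dbuf, off, blk$g)
    dense_layer_backward(blk$layers[[k]], dy, dbuf)
  }
  cpp_slice_channels(dbuf, 0L, blk$c0)
}

# ---- transition ------------------------------------------------------------

new_transition <- function(cfg, b, cin, name) {
  tr <- new.env(parent = emptyenv())
  tr$pool <- b <= 2L
  # reference design: transitions carry a 1x1 compression convolution,
  # preceded by BN+ReLU except for the last block's transition, which the
  # design leaves as a bare convolution.  The sequential ablation already
  # emits the target width, so its "transition" is pooling only.
  if (cfg$use_dense_connections) {
    tr$has_bn <- b < cfg$n_blocks
    if (tr$has_bn) tr$bn <- new_bnrelu(cin, "encoder", paste0(name, ".bn"))
    tr$conv <- new_conv(1L, 1L, cin, cfg$transition_out_channels[b],
                        group = "encoder", name = paste0(name, ".conv"))
  } else {
    tr$has_bn <- FALSE
    tr$conv <- NULL
  }
  tr
}

#' Transition forward: compress channels, then optionally pool
#'
#' @param net network.
#' @param block block index whose transition to apply.
#' @param x block output.
#' @param training training mode.
#' @param pool apply the transition's 2x2 average pooling (the network
#'   forward taps skip features before pooling, so pooling is applied
#'   separately there).
#' @param stats optional precomputed batch statistics for the BN (used by
#'   the network forward, whose block buffer stats are already known).
#' @return transition output.
#' @export
transition_forward <- function(net, block, x, training = FALSE, pool = TRUE,
                               stats = NULL) {
  tr <- net$transitions[[block]]
  y <- x
  if (!is.null(tr$conv)) {
    if (tr$has_bn) y <- bn_fwd(tr$bn, y, training, stats = stats)
    y <- conv_fwd(tr$conv, y)
  }
  if (pool && tr$pool) {
    d <- dim(y)
    if (d[1] %% 2L == 1L || d[2] %% 2L == 1L)
      warning("odd spatial size; average pooling floors the output size")
    y <- cpp_avgpool2_fwd(y)
  }
  y
}

transition_conv_backward <- function(net, block, dy) {
  tr <- net$transitions[[block]]
  if (is.null(tr$conv)) return(dy)
  if (!tr$has_bn) return(conv_bwd(tr$conv, dy))
  da <- conv_bwd(tr$conv, dy)
  dbuf <- zeros_like(tr$bn$x)
  bn_bwd(tr$bn, da, dbuf)
  dbuf
}

# ---- pyramid pooling module -----------------------------------------------

new_ppm <- function(cfg, cin, name = "ppm") {
  ppm <- new.env(parent = emptyenv())
  ppm$bins <- cfg$ppm_bins
  ppm$cin <- as.integer(cin)
  ppm$branch_bn <- list()
  ppm$branch_conv <- list()
  for (i in seq_along(ppm$bins)) {
    ppm$branch_bn[[i]] <- new_bnrelu(cin, "encoder",
                                     sprintf("%s.b%d.bn", name, i))
    ppm$branch_conv[[i]] <- new_conv(1L, 1L, cin, cfg$ppm_branch_channels,
                                     group = "encoder",
                                     name = sprintf("%s.b%d.conv", name, i))
  }
  cc <- cin + length(ppm$bins) * cfg$ppm_branch_channels
  ppm$fuse_bn <- new_bnrelu(cc, "encoder", paste0(name, ".fuse.bn"))
  ppm$fuse_conv <- new_conv(3L, 3L, cc, cfg$decoder_channels,
                            group = "encoder", name = paste0(name, ".fuse.conv"))
  ppm$cout <- cfg$decoder_channels
  ppm
}

#' Pyramid pooling forward
#'
#' Average-pools the input to each configured bin size, passes each pooled
#' map through BN+ReLU and a 1x1 convolution, upsamples it back bilinearly,
#' concatenates all branches with the input, and fuses the result with a
#' BN+ReLU+Conv3x3.  Spatial size is preserved.
#'
#' @param net network (must have been built with `use_ppm = TRUE`).
#' @param x deepest encoder feature map.
#' @param training training mode.
#' @return context feature map with `decoder_channels` channels.
#' @export
ppm_forward <- function(net, x, training = FALSE) {
  ppm <- net$ppm
  if (is.null(ppm)) stop("network was built without a pyramid pooling module")
  d <- dim(x)
  if (d[1] < max(ppm$bins) || d[2] < max(ppm$bins))
    stop("input smaller than the largest pyramid bin")
  feats <- vector("list", length(ppm$bins) + 1L)
  feats[[1]] <- x
  ppm$hdims <- vector("list", length(ppm$bins))
  for (i in seq_along(ppm$bins)) {
    p <- cpp_adaptive_avgpool_fwd(x, ppm$bins[i])
    a <- bn_fwd(ppm$branch_bn[[i]], p, training)
    h <- conv_fwd(ppm$branch_conv[[i]], a)
    ppm$hdims[[i]] <- dim(h)
    feats[[i + 1L]] <- cpp_bilinear_fwd(h, d[1], d[2])
  }
  z <- ch_cat(feats)
  ppm$zdim <- dim(z)
  a <- bn_fwd(ppm$fuse_bn, z, training)
  conv_fwd(ppm$fuse_conv, a)
}

ppm_backward <- function(net, dout) {
  ppm <- net$ppm
  da <- conv_bwd(ppm$fuse_conv, dout)
  dz <- zeros_tensor(ppm$zdim, is_ft32(dout))
  bn_bwd(ppm$fuse_bn, da, dz)
  H <- ppm$zdim[1]; W <- ppm$zdim[2]
  dx <- cpp_slice_channels(dz, 0L, ppm$cin)
  off <- ppm$cin
  nb <- dim(dz)[3] - ppm$cin
  pb <- nb / length(ppm$bins)
  for (i in seq_along(ppm$bins)) {
    du <- cpp_slice_channels(dz, off, pb)
    off <- off + pb
    hd <- ppm$hdims[[i]]
    dh <- cpp_bilinear_bwd(du, hd[1], hd[2])
    da <- conv_bwd(ppm$branch_conv[[i]], dh)
    dp <- zeros_tensor(c(hd[1], hd[2], ppm$cin, hd[4]), is_ft32(dout))
    bn_bwd(ppm$branch_bn[[i]], da, dp)
    cpp_add_inplace(dx, cpp_adaptive_avgpool_bwd(dp, H, W))
  }
  dx
}

# Concatenate tensors along the channel dimension.
ch_cat <- function(lst) {
  d <- dim(lst[[1]])
  cs <- vapply(lst, function(x) dim(x)[3], integer(1))
  out <- zeros_tensor(c(d[1], d[2], sum(cs), d[4]), is_ft32(lst[[1]]))
  off <- 0L
  for (x in lst) {
    cpp_write_channels(out, x, off)
    off <- off + dim(x)[3]
  }
  out
}

# ---- encoder forward (user-facing) ----------------------------------------

#' Run the encoder and return the feature pyramid
#'
#' @param net a network from [dcnet_network()].
#' @param image a 2-d grayscale image, or a (H, W, 1, N) tensor; spatial
#'   size must be divisible by 4 (two poolings).
#' @param training training mode (batch statistics, dropout).
#' @return a list of class `dcnet_pyramid` with elements `features` (one
#'   feature map per block, pre-pooling, so the reference configuration
#'   yields channels (80, 112, 118, 136, 16) at sizes
#'   (256, 128, 64, 64, 64) for 256x256 input), `ppm_out` (context map, or
#'   `NULL` without PPM), `channels` and `sizes`.
#' @export
encoder_forward <- function(net, image, training = FALSE) {
  x <- as_tensor(image)
  d <- dim(x)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("input spatial size must be divisible by 4, got ",
         d[1], "x", d[2])
  if (d[3] != 1L) stop("expected a single-channel input")
  if (identical(net$dtype, "single")) x <- cpp_to_f32(x)
  cur <- conv_fwd(net$stem, x)
  n <- net$config$n_blocks
  feats <- vector("list", n)
  for (b in seq_len(n)) {
    buf <- dense_block_forward(net, b, cur, training)
    feats[[b]] <- transition_forward(net, b, buf, training, pool = FALSE,
                                     stats = net$blocks[[b]]$stats)
    net$blocks[[b]]$bufdim <- dim(buf)
    cur <- if (net$transitions[[b]]$pool) cpp_avgpool2_fwd(feats[[b]])
           else feats[[b]]
  }
  structure(list(
    features = feats,
    ppm_out = if (net$config$use_ppm) ppm_forward(net, feats[[n]], training)
              else NULL,
    channels = vapply(feats, function(f) dim(f)[3], integer(1)),
    sizes = vapply(feats, function(f) dim(f)[1], integer(1))
  ), class = "dcnet_pyramid")
}
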