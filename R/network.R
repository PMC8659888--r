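# Full network: builder, forward pass producing the multi-level outputs
# S0..Sn, and the hand-rolled reverse-mode backward pass.

#' Build a segmentation network
#'
#' Constructs the encoder-decoder network described by a [dcnet_config()]:
#' a 3x3 stem, `n_blocks` dense blocks with transitions (2x2 average
#' pooling after the first two), optionally the pyramid pooling module on
#' the deepest feature map, 1x1 skip-compression convolutions to
#' `skip_channels`, one decoder fusion level per skip (BN+ReLU+Conv3x3 on
#' the concatenation of the upsampled deeper feature and the skip), a
#' 1-channel sigmoid head per decoder level, and a BN+ReLU+Conv3x3 fusion
#' of all head logits into the final map S0.
#'
#' @param config a [dcnet_config()] (default: the reference variant A).
#' @param seed optional integer seed for the parameter initialization
#'   (He-normal weights).
#' @return an object of class `dcnet`.
#' @export
dcnet_network <- function(config = dcnet_config(), seed = NULL) {
  if (!inherits(config, "dcnet_config")) stop("config must be a dcnet_config")
  if (!is.null(seed)) set.seed(seed)
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$dtype <- config$precision
  n <- config$n_blocks
  net$stem <- new_conv(3L, 3L, 1L, config$stem_channels,
                       group = "encoder", name = "stem")
  net$blocks <- vector("list", n)
  net$transitions <- vector("list", n)
  cin <- config$stem_channels
  for (b in seq_len(n)) {
    net$blocks[[b]] <- new_block(config, b, cin, sprintf("enc.db%d", b))
    net$transitions[[b]] <- new_transition(config, b, net$blocks[[b]]$cout,
                                           sprintf("enc.tr%d", b))
    cin <- config$transition_out_channels[b]
  }
  deep_ch <- config$transition_out_channels[n]
  if (config$use_ppm) {
    net$ppm <- new_ppm(config, deep_ch)
    deep_ch <- net$ppm$cout
  } else {
    net$ppm <- NULL
  }
  w <- config$decoder_channels
  sk <- config$skip_channels
  net$skips <- vector("list", n - 1L)
  net$levels <- vector("list", n - 1L)
  net$heads <- vector("list", n)
  prev <- deep_ch
  for (k in rev(seq_len(n - 1L))) {
    if (config$use_skip)
      net$skips[[k]] <- new_conv(1L, 1L, config$transition_out_channels[k], sk,
                                 group = "decoder",
                                 name = sprintf("dec.skip%d", k))
    lvl <- new.env(parent = emptyenv())
    cc <- if (config$use_skip) prev + sk else prev
    lvl$bn <- new_bnrelu(cc, "decoder", sprintf("dec.l%d.bn", k))
    lvl$conv <- new_conv(3L, 3L, cc, w, group = "decoder",
                         name = sprintf("dec.l%d.conv", k))
    net$levels[[k]] <- lvl
    prev <- w
  }
  net$heads[[n]] <- new_conv(1L, 1L, deep_ch, 1L, group = "decoder",
                             name = sprintf("dec.head%d", n))
  for (k in seq_len(n - 1L))
    net$heads[[k]] <- new_conv(1L, 1L, w, 1L, group = "decoder",
                               name = sprintf("dec.head%d", k))
  net$fuse_bn <- new_bnrelu(n, "decoder", "dec.fuse.bn")
  net$fuse_conv <- new_conv(3L, 3L, n, 1L, group = "decoder",
                            name = "dec.fuse.conv")
  # class-prior bias initialization: tumors cover a small fraction of a
  # slice, so heads start near that prior instead of at p = 0.5
  for (k in seq_len(n)) net$heads[[k]]$b[] <- -3
  net$fuse_conv$b[] <- -3
  # flat registry of the leaves, used by the optimizer/freezing/state I/O
  leaves <- list(net$stem)
  for (b in seq_len(n)) {
    for (lay in net$blocks[[b]]$layers)
      leaves <- c(leaves, list(lay$bn1, lay$conv1, lay$bn2, lay$conv2))
    tr <- net$transitions[[b]]
    if (isTRUE(tr$has_bn)) leaves <- c(leaves, list(tr$bn))
    if (!is.null(tr$conv)) leaves <- c(leaves, list(tr$conv))
  }
  if (!is.null(net$ppm))
    leaves <- c(leaves, net$ppm$branch_bn, net$ppm$branch_conv,
                list(net$ppm$fuse_bn, net$ppm$fuse_conv))
  if (config$use_skip) leaves <- c(leaves, net$skips)
  for (lvl in net$levels) leaves <- c(leaves, list(lvl$bn, lvl$conv))
  leaves <- c(leaves, net$heads, list(net$fuse_bn, net$fuse_conv))
  net$modules <- stats::setNames(leaves,
                                 vapply(leaves, function(m) m$name, ""))
  class(net) <- "dcnet"
  net
}

#' @export
print.dcnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dcnet> %d dense blocks (growth %d x %d layers)%s%s\n",
              cfg$n_blocks, cfg$growth_rate, cfg$layers_per_block,
              if (cfg$use_ppm) ", PPM" else "",
              if (cfg$use_skip) ", skips" else ""))
  cat(sprintf("  transition channels: %s\n",
              paste(cfg$transition_out_channels, collapse = ", ")))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Compress an encoder feature map for a skip connection
#'
#' Applies the level-`k` 1x1 skip convolution, reducing any encoder level
#' to `skip_channels` (16) channels at unchanged spatial size.
#'
#' @param net network.
#' @param k encoder level index (1 to `n_blocks - 1`).
#' @param y feature map from that level.
#' @return compressed feature map.
#' @export
compress_skip <- function(net, k, y) {
  conv_fwd(net$skips[[k]], as_tensor(y))
}

#' Threshold a probability map into a binary mask
#'
#' Pixels with probability greater than or equal to the threshold are
#' foreground; the tie at exactly 0.5 is assigned to foreground.
#'
#' @param S probability map (any array, values in \[0, 1\]).
#' @param threshold classification threshold (default 0.5).
#' @return integer array of 0/1 with the same shape.
#' @export
binarize <- function(S, threshold = 0.5) {
  out <- if (is.null(dim(S))) integer(length(S)) else array(0L, dim(S))
  out[S >= threshold] <- 1L
  out
}

#' Full forward pass: multi-level probability maps
#'
#' Runs encoder, pyramid pooling and decoder, returning one probability
#' map per supervision level, all bilinearly upsampled to the input
#' resolution and squashed by a sigmoid.  `S0` is the fused prediction
#' used for segmentation; `S1` (shallowest) to `Sn` (deepest, produced
#' from the pyramid pooling output alone) are the per-level side outputs.
#'
#' @param net network.
#' @param image 2-d image or (H, W, 1, N) tensor, values in \[0, 1\],
#'   spatial size divisible by 4.
#' @param training training mode.
#' @return an object of class `dcnet_output`: list with `probs` and
#'   `logits` (named lists S0..Sn of (H, W, 1, N) arrays) and `n_levels`.
#' @export
dcnet_forward <- function(net, image, training = FALSE) {
  x <- as_tensor(image)
  H <- dim(x)[1]; W <- dim(x)[2]
  pyr <- encoder_forward(net, x, training)
  n <- net$config$n_blocks
  cfg <- net$config
  cache <- new.env(parent = emptyenv())
  net$cache <- cache
  deep <- if (cfg$use_ppm) pyr$ppm_out else pyr$features[[n]]
  cache$tdims <- vector("list", n - 1L)
  ts <- vector("list", n - 1L)
  if (cfg$use_skip) {
    for (k in seq_len(n - 1L))
      ts[[k]] <- conv_fwd(net$skips[[k]], pyr$features[[k]])
  }
  logits <- vector("list", n + 1L)
  d <- deep
  cache$ddims <- vector("list", n)
  cache$zdims <- vector("list", n - 1L)
  cache$lv_sizes <- pyr$sizes
  cache$ddims[[n]] <- dim(d)
  hl <- conv_fwd(net$heads[[n]], d)
  cache$hdims <- vector("list", n)
  cache$hdims[[n]] <- dim(hl)
  logits[[n + 1L]] <- if (dim(hl)[1] == H && dim(hl)[2] == W) hl
                      else cpp_bilinear_fwd(hl, H, W)
  for (k in rev(seq_len(n - 1L))) {
    tgt <- pyr$sizes[k]
    u <- if (dim(d)[1] == tgt && dim(d)[2] == tgt) d
         else cpp_bilinear_fwd(d, tgt, tgt)
    z <- if (cfg$use_skip) ch_cat(list(u, ts[[k]])) else u
    cache$zdims[[k]] <- dim(z)
    lvl <- net$levels[[k]]
    a <- bn_fwd(lvl$bn, z, training)
    d <- conv_fwd(lvl$conv, a)
    cache$ddims[[k]] <- dim(d)
    hl <- conv_fwd(net$heads[[k]], d)
    cache$hdims[[k]] <- dim(hl)
    logits[[k + 1L]] <- if (dim(hl)[1] == H && dim(hl)[2] == W) hl
                        else cpp_bilinear_fwd(hl, H, W)
  }
  Z <- ch_cat(logits[seq_len(n) + 1L])
  cache$Zdim <- dim(Z)
  cache$ft <- is_ft32(Z)
  a <- bn_fwd(net$fuse_bn, Z, training)
  logits[[1L]] <- conv_fwd(net$fuse_conv, a)
  names(logits) <- paste0("S", 0:n)
  logits <- lapply(logits, as_array)
  probs <- lapply(logits, sigmoid)
  structure(list(probs = probs, logits = logits, n_levels = n,
                 input_size = c(H, W)),
            class = "dcnet_output")
}

# Reverse pass: `dlogits` is a named list S0..Sn of gradients with respect
# to the pre-sigmoid logit maps (any entry may be NULL).  Accumulates
# parameter gradients in the modules.
dcnet_backward <- function(net, dlogits) {
  cfg <- net$config
  n <- cfg$n_blocks
  cache <- net$cache
  H <- cache$Zdim[1]; W <- cache$Zdim[2]
  zero_full <- NULL
  getd <- function(i) {
    x <- dlogits[[paste0("S", i)]]
    if (is.null(x)) {
      if (is.null(zero_full))
        zero_full <<- zeros_tensor(c(H, W, 1L, cache$Zdim[4]), cache$ft)
      return(zero_full)
    }
    if (cache$ft) cpp_to_f32(x) else x
  }
  # fused head
  da <- conv_bwd(net$fuse_conv, getd(0L))
  dZ <- zeros_tensor(cache$Zdim, cache$ft)
  bn_bwd(net$fuse_bn, da, dZ)
  dy_inj <- vector("list", n)  # gradients entering each encoder level
  carry <- NULL                # gradient flowing into the next-deeper d
  for (k in seq_len(n - 1L)) {
    dLk <- cpp_slice_channels(dZ, k - 1L, 1L)
    cpp_add_inplace(dLk, getd(k))
    hd <- cache$hdims[[k]]
    dhl <- if (hd[1] == H && hd[2] == W) dLk else cpp_bilinear_bwd(dLk, hd[1], hd[2])
    dd <- conv_bwd(net$heads[[k]], dhl)
    if (!is.null(carry)) cpp_add_inplace(dd, carry)
    lvl <- net$levels[[k]]
    da <- conv_bwd(lvl$conv, dd)
    dz <- zeros_tensor(cache$zdims[[k]], cache$ft)
    bn_bwd(lvl$bn, da, dz)
    prev_w <- cache$ddims[[k + 1L]][3]
    if (cfg$use_skip) {
      du <- cpp_slice_channels(dz, 0L, prev_w)
      dt <- cpp_slice_channels(dz, prev_w, dim(dz)[3] - prev_w)
      dy_inj[[k]] <- conv_bwd(net$skips[[k]], dt,
                              want_dx = !isTRUE(net$enc_frozen))
    } else {
      du <- dz
    }
    dd_deeper <- cache$ddims[[k + 1L]]
    carry <- if (dim(du)[1] == dd_deeper[1] && dim(du)[2] == dd_deeper[2]) du
             else cpp_bilinear_bwd(du, dd_deeper[1], dd_deeper[2])
  }
  # deepest level
  dLn <- cpp_slice_channels(dZ, n - 1L, 1L)
  cpp_add_inplace(dLn, getd(n))
  hd <- cache$hdims[[n]]
  dhl <- if (hd[1] == H && hd[2] == W) dLn else cpp_bilinear_bwd(dLn, hd[1], hd[2])
  dd <- conv_bwd(net$heads[[n]], dhl)
  if (!is.null(carry)) cpp_add_inplace(dd, carry)
  # a fully frozen encoder receives no parameter updates, so gradients
  # need not be propagated into it at all (stage 2 of the training
  # protocol); this prunes most of the backward cost of that stage
  if (isTRUE(net$enc_frozen)) return(invisible(net))
  dy_n <- if (cfg$use_ppm) ppm_backward(net, dd) else dd
  if (is.null(dy_inj[[n]])) dy_inj[[n]] <- dy_n else
    cpp_add_inplace(dy_inj[[n]], dy_n)
  # encoder chain
  dfeat <- dy_inj[[n]]
  for (b in rev(seq_len(n))) {
    dbuf <- transition_conv_backward(net, b, dfeat)
    din <- dense_block_backward(net, b, dbuf)
    if (b > 1L) {
      dprev <- if (net$transitions[[b - 1L]]$pool)
        cpp_avgpool2_bwd(din, dim(din)[1] * 2L, dim(din)[2] * 2L)
      else din
      dfeat <- dprev
      if (!is.null(dy_inj[[b - 1L]])) cpp_add_inplace(dfeat, dy_inj[[b - 1L]])
    } else {
      conv_bwd(net$stem, din, want_dx = FALSE)
    }
  }
  invisible(net)
}
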