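#' Network configuration
#'
#' Assembles and validates the hyper-parameters that define the encoder and
#' decoder topology.  Defaults reproduce the reference architecture: five
#' dense blocks of 12 layers with growth rate 12, transition outputs
#' (80, 112, 118, 136, 16), 2x2 average pooling after the first two blocks,
#' a PSPNet-style pyramid pooling module with bins (1, 2, 3, 6), skip
#' connections compressed to 16 channels, and one supervised sigmoid head
#' per decoder level plus a fused head.  The stem, bottleneck, pyramid
#' branch and decoder fusion widths are the free widths of the design; the
#' defaults place the trainable parameter count at the published 0.28 M
#' budget (within 2%).
#'
#' @param growth_rate channels added by each dense layer (default 12).
#' @param layers_per_block convolutional layers per dense block (default 12).
#' @param n_blocks number of dense blocks, 4, 5 or 6 (5 is the reference;
#'   4 and 6 are the ablation topologies).
#' @param drop_rate dropout rate after each dense-layer convolution.
#' @param dilation_schedule per-block dilation factor for the 3x3
#'   convolutions; default 1 for the first two blocks (which still pool)
#'   and 2 afterwards.
#' @param transition_out_channels channels after each block's transition
#'   convolution; defaults to the published schedule for the chosen
#'   `n_blocks`.
#' @param use_ppm include the pyramid pooling module (off = variant B).
#' @param use_skip include skip connections (off = variant C).
#' @param use_dense_connections dense concatenation within blocks
#'   (off = variant G, plain sequential blocks).
#' @param single_loss supervise only the fused output, loss `6 J(S0)`
#'   (variant F).
#' @param stem_channels width of the 3x3 stem convolution feeding block 1.
#' @param bottleneck_channels width of the 1x1 channel-mixing convolution
#'   inside each dense layer, ahead of the dilated 3x3 convolution.
#' @param ppm_bins pyramid pooling bin sizes.
#' @param ppm_branch_channels channels of each pyramid branch after its
#'   1x1 convolution.
#' @param skip_channels channels each skip connection is compressed to
#'   (16 in the reference design).
#' @param decoder_channels width of the decoder fusion features.
#' @param bn_momentum,bn_eps batch-normalization running-moment momentum
#'   and variance stabilizer.
#' @param precision working precision of activations and activation
#'   gradients: `"single"` (default; master weights, parameter gradients
#'   and batch-norm statistics stay in double) or `"double"` (used by the
#'   exact finite-difference gradient tests).
#' @return an object of class `dcnet_config`.
#' @seealso [dcnet_variant()] for the named ablation presets.
#' @export
dcnet_config <- function(growth_rate = 12L, layers_per_block = 12L,
                         n_blocks = 5L, drop_rate = 0.2,
                         dilation_schedule = NULL,
                         transition_out_channels = NULL,
                         use_ppm = TRUE, use_skip = TRUE,
                         use_dense_connections = TRUE, single_loss = FALSE,
                         stem_channels = 16L, bottleneck_channels = 8L,
                         ppm_bins = c(1L, 2L, 3L, 6L),
                         ppm_branch_channels = 4L, skip_channels = 16L,
                         decoder_channels = 12L, bn_momentum = 0.1,
                         bn_eps = 1e-5, precision = c("single", "double")) {
  precision <- match.arg(precision)
  n_blocks <- as.integer(n_blocks)
  if (!n_blocks %in% 4:6) stop("n_blocks must be 4, 5 or 6")
  if (growth_rate < 1L || layers_per_block < 1L)
    stop("growth_rate and layers_per_block must be >= 1")
  if (is.null(transition_out_channels)) {
    transition_out_channels <- switch(as.character(n_blocks),
      "4" = c(80L, 112L, 118L, 136L),
      "5" = c(80L, 112L, 118L, 136L, 16L),
      # the six-block ablation appends a 140-channel block between the last
      # reference block and the pyramid pooling module
      "6" = c(80L, 112L, 118L, 136L, 16L, 140L))
  }
  if (length(transition_out_channels) != n_blocks)
    stop("transition_out_channels must have n_blocks entries")
  if (is.null(dilation_schedule))
    dilation_schedule <- c(1L, 1L, rep(2L, n_blocks - 2L))
  if (length(dilation_schedule) != n_blocks)
    stop("dilation_schedule must have n_blocks entries")
  if (drop_rate < 0 || drop_rate >= 1) stop("drop_rate must be in [0, 1)")
  cfg <- list(growth_rate = as.integer(growth_rate),
              layers_per_block = as.integer(layers_per_block),
              n_blocks = n_blocks, drop_rate = drop_rate,
              dilation_schedule = as.integer(dilation_schedule),
              transition_out_channels = as.integer(transition_out_channels),
              use_ppm = isTRUE(use_ppm), use_skip = isTRUE(use_skip),
              use_dense_connections = isTRUE(use_dense_connections),
              single_loss = isTRUE(single_loss),
              stem_channels = as.integer(stem_channels),
              bottleneck_channels = as.integer(bottleneck_channels),
              ppm_bins = as.integer(ppm_bins),
              ppm_branch_channels = as.integer(ppm_branch_channels),
              skip_channels = as.integer(skip_channels),
              decoder_channels = as.integer(decoder_channels),
              bn_momentum = bn_momentum, bn_eps = bn_eps,
              precision = precision)
  structure(cfg, class = "dcnet_config")
}

#' Ablation variant presets
#'
#' Named presets for the reference network (A) and its ablations:
#' B removes the pyramid pooling module, C the skip connections, D uses
#' four dense blocks, E six, F supervises only the fused output, and G
#' removes the dense connections within blocks.
#'
#' @param variant one of `"A"` to `"G"`.
#' @param ... further arguments passed to [dcnet_config()].
#' @return a `dcnet_config`.
#' @export
dcnet_variant <- function(variant = c("A", "B", "C", "D", "E", "F", "G"),
                          ...) {
  variant <- match.arg(variant)
  args <- switch(variant,
                 A = list(),
                 B = list(use_ppm = FALSE),
                 C = list(use_skip = FALSE),
                 D = list(n_blocks = 4L),
                 E = list(n_blocks = 6L),
                 F = list(single_loss = TRUE),
                 G = list(use_dense_connections = FALSE))
  cfg <- do.call(dcnet_config, utils::modifyList(args, list(...)))
  cfg$variant <- variant
  cfg
}
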