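# Architecture tests run on a reduced configuration (tiny_config) wherever
# the property does not depend on the reference widths; the published
# channel/size schedule itself is checked in the acceptance suite at full
# size.

test_that("dense layer emits growth channels at unchanged size", {
  set.seed(41)
  lay <- new_dense_layer(5L, growth = 12L, bottleneck = 3L, dilation = 2L)
  x <- array(runif(24 * 24 * 5), c(24, 24, 5, 2))
  y <- dense_layer_forward(lay, x)
  expect_equal(dim(y), c(24L, 24L, 12L, 2L))
  lay1 <- new_dense_layer(4L, growth = 1L, bottleneck = 2L)
  expect_equal(dim(dense_layer_forward(lay1, array(runif(64 * 4), c(8, 8, 4, 1))))[3], 1L)
})

test_that("dilated convolution has the expected receptive footprint", {
  # impulse response of a single 3x3 conv with dilation 2 covers a 5x5
  # dilated footprint: the 9 taps at offsets {-2, 0, 2}^2
  w <- array(1, c(3, 3, 1, 1))
  x <- array(0, c(15, 15, 1, 1))
  x[8, 8, 1, 1] <- 1
  y <- dcnet:::cpp_conv_fwd(x, w, numeric(1), 2L)
  nz <- which(y[, , 1, 1] != 0, arr.ind = TRUE)
  expect_setequal(nz[, 1], c(6, 8, 10))
  expect_setequal(nz[, 2], c(6, 8, 10))
  expect_equal(nrow(nz), 9)
  # same-padding contract: dilation never changes the spatial size
  for (d in 1:3) {
    y2 <- dcnet:::cpp_conv_fwd(array(runif(15 * 15), c(15, 15, 1, 1)),
                               w, numeric(1), d)
    expect_equal(dim(y2)[1:2], c(15L, 15L))
  }
})

test_that("dense block channel bookkeeping follows the concatenation rule", {
  set.seed(42)
  net <- dcnet_network(tiny_config(precision = "double"), seed = 1)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4, 1))
  buf <- dense_block_forward(net, 1, x)
  # input channels + layers x growth = 4 + 2 * 3
  expect_equal(dim(buf)[3], 4L + 2L * 3L)
  expect_equal(dim(buf)[1:2], c(16L, 16L))
  # the first channels are the unchanged input
  expect_equal(buf[, , 1:4, , drop = FALSE], x)
  # reference arithmetic: 16 input channels, 12 layers x growth 12 -> 160
  cfg <- dcnet_config()
  expect_equal(cfg$stem_channels + cfg$layers_per_block * cfg$growth_rate,
               160L)
})

test_that("transitions compress channels and pool where scheduled", {
  set.seed(43)
  net <- dcnet_network(tiny_config(precision = "double"), seed = 1)
  buf <- array(runif(16 * 16 * 10), c(16, 16, 10, 1))
  y <- transition_forward(net, 1, buf)          # pool = TRUE for block 1
  expect_equal(dim(y), c(8L, 8L, 6L, 1L))
  y2 <- transition_forward(net, 1, buf, pool = FALSE)
  expect_equal(dim(y2), c(16L, 16L, 6L, 1L))
  # 2x2 average pooling of a constant stays that constant
  cst <- array(2.5, c(8, 8, 3, 1))
  expect_equal(as_array(dcnet:::cpp_avgpool2_fwd(cst)),
               array(2.5, c(4, 4, 3, 1)))
})

test_that("pyramid pooling preserves size and the bin-1 branch is the mean", {
  set.seed(44)
  net <- dcnet_network(tiny_config(precision = "double"), seed = 1)
  c5 <- net$config$transition_out_channels[5]
  x <- array(runif(8 * 8 * c5), c(8, 8, c5, 1))
  out <- ppm_forward(net, x)
  expect_equal(dim(out)[1:2], c(8L, 8L))
  expect_equal(dim(out)[3], net$config$decoder_channels)
  # bin-1 branch before its convolution equals the global mean, replicated
  p <- dcnet:::cpp_adaptive_avgpool_fwd(x, 1L)
  for (c in seq_len(c5)) expect_equal(p[1, 1, c, 1], mean(x[, , c, 1]))
  up <- dcnet:::cpp_bilinear_fwd(p, 8L, 8L)
  expect_equal(up[, , 1, 1], matrix(mean(x[, , 1, 1]), 8, 8))
  # constant input: every pooled branch is that constant
  cst <- array(1.3, c(8, 8, c5, 1))
  for (b in c(1L, 2L)) {
    pb <- dcnet:::cpp_adaptive_avgpool_fwd(cst, b)
    expect_equal(as.vector(pb), rep(1.3, b * b * c5))
  }
  expect_error(ppm_forward(net, x[1:1, 1:1, , , drop = FALSE]),
               "largest pyramid bin")
})

test_that("encoder pyramid shapes scale with the input and ablate correctly", {
  set.seed(45)
  net <- dcnet_network(tiny_config(), seed = 1)
  pyr <- encoder_forward(net, matrix(runif(32 * 32), 32, 32))
  expect_equal(pyr$channels, c(6L, 7L, 8L, 9L, 5L))
  expect_equal(pyr$sizes, c(32L, 16L, 8L, 8L, 8L))
  expect_true(all(diff(pyr$sizes) <= 0))
  expect_error(encoder_forward(net, matrix(0, 30, 30)), "divisible by 4")
  # four-block ablation topology
  net4 <- dcnet_network(tiny_config(n_blocks = 4L,
                                    transition_out_channels = c(6L, 7L, 8L, 9L)),
                        seed = 1)
  pyr4 <- encoder_forward(net4, matrix(runif(32 * 32), 32, 32))
  expect_length(pyr4$features, 4)
  expect_equal(pyr4$sizes, c(32L, 16L, 8L, 8L))
  # six-block ablation appends a block between the last and the PPM
  net6 <- dcnet_network(tiny_config(n_blocks = 6L,
                                    transition_out_channels = c(6L, 7L, 8L, 9L, 5L, 10L)),
                        seed = 1)
  pyr6 <- encoder_forward(net6, matrix(runif(32 * 32), 32, 32))
  expect_equal(pyr6$channels[6], 10L)
  expect_equal(pyr6$sizes[6], 8L)
})

test_that("no-PPM and no-dense ablations change the module graph", {
  netB <- dcnet_network(tiny_config(use_ppm = FALSE), seed = 1)
  expect_null(netB$ppm)
  expect_false(any(grepl("^ppm", names(netB$modules))))
  outB <- dcnet_forward(netB, matrix(runif(16 * 16), 16, 16))
  expect_length(outB$probs, 6)
  netG <- dcnet_network(tiny_config(use_dense_connections = FALSE), seed = 1)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4, 1))
  bufG <- dense_block_forward(netG, 1, x)
  # sequential block emits the transition width directly
  expect_equal(dim(bufG)[3], netG$config$transition_out_channels[1])
  outG <- dcnet_forward(netG, matrix(runif(16 * 16), 16, 16))
  expect_length(outG$probs, 6)
})

test_that("count_parameters is exact on closed-form cases and additive", {
  # single k x k conv with bias: cout * (cin * k^2 + 1)
  m <- dcnet:::new_conv(3L, 3L, 4L, 7L)
  expect_equal(count_parameters(m), 7L * (4L * 9L + 1L))
  net <- dcnet_network(tiny_config(), seed = 1)
  total <- count_parameters(net)
  enc <- sum(vapply(module_list(net), function(m)
    if (m$group == "encoder") sum(lengths(lapply(m$param_names, function(p) m[[p]])))
    else 0L, 0))
  freeze(net, "decoder")
  expect_equal(count_parameters(net), as.integer(enc))
  freeze(net, "none")
  expect_equal(count_parameters(net), total)
})

test_that("decoder emits full-resolution probability maps at every level", {
  set.seed(46)
  net <- dcnet_network(tiny_config(), seed = 1)
  out <- dcnet_forward(net, matrix(runif(32 * 32), 32, 32))
  expect_length(out$probs, 6)
  expect_named(out$probs, paste0("S", 0:5))
  for (p in out$probs) {
    expect_equal(dim(p)[1:2], c(32L, 32L))
    expect_true(all(p >= 0 & p <= 1))
  }
  # output shape invariance for any input size divisible by 4
  out2 <- dcnet_forward(net, matrix(runif(20 * 20), 20, 20))
  expect_equal(dim(out2$probs$S0)[1:2], c(20L, 20L))
})

test_that("skip compression maps any encoder level to skip_channels", {
  set.seed(47)
  net <- dcnet_network(tiny_config(), seed = 1)
  pyr <- encoder_forward(net, matrix(runif(32 * 32), 32, 32))
  for (k in 1:4) {
    t <- compress_skip(net, k, pyr$features[[k]])
    expect_equal(dim(t)[3], net$config$skip_channels)
    expect_equal(dim(t)[1:2], dim(pyr$features[[k]])[1:2])
  }
  # passes through a convolution even when widths already match: the
  # output must differ from the input
  net16 <- dcnet_network(tiny_config(skip_channels = 6L), seed = 2)
  pyr16 <- encoder_forward(net16, matrix(runif(32 * 32), 32, 32))
  t1 <- compress_skip(net16, 1, pyr16$features[[1]])
  expect_false(isTRUE(all.equal(as_array(t1), as_array(pyr16$features[[1]]))))
})

test_that("binarization thresholds at 0.5 with ties to foreground", {
  expect_equal(unique(as.vector(binarize(matrix(0.6, 3, 3)))), 1L)
  expect_equal(unique(as.vector(binarize(matrix(0.4, 3, 3)))), 0L)
  expect_equal(binarize(0.5), 1L)                 # declared tie convention
  set.seed(48)
  S <- matrix(runif(64), 8, 8)
  b <- binarize(S)
  expect_identical(binarize(b, 0.5), b)           # idempotent re-threshold
})

test_that("the deepest head depends only on deep features", {
  # S5 is produced from the pyramid pooling output alone: zeroing the
  # shallow skip paths must leave it unchanged
  set.seed(49)
  net <- dcnet_network(tiny_config(), seed = 1)
  x <- matrix(runif(32 * 32), 32, 32)
  out1 <- dcnet_forward(net, x)
  for (k in seq_along(net$skips)) {
    if (!is.null(net$skips[[k]])) net$skips[[k]]$w[] <- 0
  }
  out2 <- dcnet_forward(net, x)
  expect_equal(out2$probs$S5, out1$probs$S5)
  expect_false(isTRUE(all.equal(out2$probs$S1, out1$probs$S1)))
})

test_that("no-skip variant consumes only upsampled deeper features", {
  netC <- dcnet_network(tiny_config(use_skip = FALSE), seed = 3)
  expect_true(all(vapply(netC$skips, is.null, TRUE)))
  out <- dcnet_forward(netC, matrix(runif(32 * 32), 32, 32))
  expect_length(out$probs, 6)
  expect_equal(dim(out$probs$S0)[1:2], c(32L, 32L))
})

test_that("single and double precision paths agree", {
  set.seed(50)
  x <- matrix(runif(32 * 32), 32, 32)
  nf <- dcnet_network(tiny_config(precision = "single"), seed = 9)
  nd <- dcnet_network(tiny_config(precision = "double"), seed = 9)
  of <- dcnet_forward(nf, x)
  od <- dcnet_forward(nd, x)
  expect_equal(of$probs$S0, od$probs$S0, tolerance = 1e-5)
  expect_equal(of$probs$S5, od$probs$S5, tolerance = 1e-5)
})

test_that("network backward matches finite-difference gradients", {
  set.seed(51)
  cfg <- tiny_config(precision = "double")
  net <- dcnet_network(cfg, seed = 4)
  H <- 16
  x <- array(runif(H * H * 2), c(H, H, 1, 2))
  G <- array(0, c(H, H, 1, 2))
  G[5:9, 6:10, 1, 1] <- 1
  G[2:4, 3:5, 1, 2] <- 1
  lcfg <- loss_config(lambda = 0)  # omega is detached by design
  loss_of <- function() {
    out <- dcnet_forward(net, x, training = TRUE)
    integrated_loss(out, G, lcfg)
  }
  out <- dcnet_forward(net, x, training = TRUE)
  dl <- dcnet:::integrated_loss_grad(out, G, lcfg)
  dcnet:::zero_grads(net)
  dcnet:::dcnet_backward(net, dl)
  gn <- c(w = "gw", b = "gb", gamma = "ggamma", beta = "gbeta")
  eps <- 1e-5
  mods <- module_list(net)
  set.seed(52)
  for (nm in sample(names(mods), 12)) {
    m <- mods[[nm]]
    for (p in m$param_names) {
      i <- sample(length(m[[p]]), 1)
      v0 <- m[[p]][i]
      m[[p]][i] <- v0 + eps
      lp <- loss_of()
      m[[p]][i] <- v0 - eps
      lm <- loss_of()
      m[[p]][i] <- v0
      num <- (lp - lm) / (2 * eps)
      ana <- m[[gn[[p]]]][i]
      expect_equal(ana, num, tolerance = 5e-3,
                   label = paste0(nm, "$", p, " analytic gradient"))
    }
  }
})
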