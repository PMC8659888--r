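test_that("weighted cross entropy matches hand evaluation", {
  cfg1 <- loss_config(lambda = 1)
  # G = [1, 0], P = [0.5, 0.5]: V = 2, V_P1 = 1, omega = 1 -> CE = log 2
  expect_equal(weighted_ce(c(0.5, 0.5), c(1, 0), cfg1), log(2))
  # all-background truth at P = 0.5: the foreground term vanishes
  expect_equal(weighted_ce(rep(0.5, 16), rep(0, 16), cfg1), log(2))
  # perfect prediction (clamped at 1 - eps) -> CE ~ 0
  G <- c(1, 1, 0, 0)
  expect_lt(weighted_ce(G, G, cfg1), 1e-4)
  expect_error(weighted_ce(c(0.5, 1.2), c(1, 0), cfg1), "\\[0, 1\\]")
})

test_that("generalized dice loss matches hand evaluation and bounds", {
  cfg <- loss_config()
  # G = [1, 0], P = [0.5, 0.5]: w1 = w0 = 1, num = 1, den = 4 -> DL = 0.5
  expect_equal(generalized_dice_loss(c(0.5, 0.5), c(1, 0), cfg), 0.5)
  G <- c(1, 0, 0, 1)
  expect_equal(generalized_dice_loss(G, G, cfg), 0)        # perfect overlap
  expect_equal(generalized_dice_loss(1 - G, G, cfg), 1)    # total miss
  set.seed(20)
  for (i in 1:100) {
    P <- runif(64)
    G <- as.numeric(runif(64) < 0.3)
    dl <- generalized_dice_loss(P, G, cfg)
    expect_gte(dl, 0)
    expect_lte(dl, 1)
  }
})

test_that("combined loss is additive and the toy cases sum", {
  cfg1 <- loss_config(lambda = 1)
  expect_equal(combined_loss(c(0.5, 0.5), c(1, 0), cfg1), log(2) + 0.5)
  G <- c(1, 0, 1, 0)
  expect_lt(combined_loss(G, G, cfg1), 1e-4)
  set.seed(21)
  for (i in 1:50) {
    P <- runif(32); G <- as.numeric(runif(32) < 0.4)
    expect_gte(combined_loss(P, G, cfg1), 0)
  }
})

test_that("losses agree with brute-force per-pixel oracles", {
  set.seed(22)
  for (i in 1:300) {
    n <- sample(c(64, 144, 256), 1)  # 8x8 .. 16x16
    P <- runif(n)
    G <- as.numeric(runif(n) < runif(1, 0.05, 0.5))
    expect_equal(weighted_ce(P, G, loss_config(lambda = 1)),
                 oracle_weighted_ce(P, G), tolerance = 1e-10)
    expect_equal(generalized_dice_loss(P, G), oracle_gdl(P, G),
                 tolerance = 1e-10)
  }
})

test_that("losses decrease as P moves toward the binary truth", {
  set.seed(23)
  cfg <- loss_config(lambda = 1)
  for (i in 1:40) {
    G <- as.numeric(runif(64) < 0.3)
    if (sum(G) == 0) G[1] <- 1
    P0 <- runif(64, 0.05, 0.95)
    tpath <- seq(0, 0.95, by = 0.05)
    ce <- dl <- numeric(length(tpath))
    for (j in seq_along(tpath)) {
      P <- (1 - tpath[j]) * P0 + tpath[j] * G
      ce[j] <- weighted_ce(P, G, cfg)
      dl[j] <- generalized_dice_loss(P, G, cfg)
    }
    expect_true(all(diff(dl) <= 1e-9))
    expect_true(all(diff(ce) <= 1e-6))
  }
})

test_that("integrated loss sums levels and honours single-loss mode", {
  set.seed(24)
  H <- 8
  G <- array(as.numeric(runif(H * H) < 0.3), c(H, H, 1, 1))
  mk <- function() array(runif(H * H), c(H, H, 1, 1))
  probs <- list(S0 = mk(), S1 = mk(), S2 = mk(), S3 = mk(), S4 = mk(),
                S5 = mk())
  cfg <- loss_config()
  # identical maps: the sum equals 6 J(S0)
  same <- probs
  for (k in 2:6) same[[k]] <- same$S0
  expect_equal(integrated_loss(same, G, cfg),
               6 * combined_loss(same$S0[, , 1, 1], G[, , 1, 1], cfg))
  # explicit per-level sum
  expect_equal(integrated_loss(probs, G, cfg),
               sum(vapply(probs, function(p)
                 combined_loss(p[, , 1, 1], G[, , 1, 1], cfg), 0)))
  # single-loss mode ignores S1..S5 entirely
  cfgF <- loss_config(single_loss = TRUE)
  perturbed <- probs
  perturbed$S3 <- mk()
  expect_equal(integrated_loss(probs, G, cfgF),
               integrated_loss(perturbed, G, cfgF))
  expect_equal(integrated_loss(probs, G, cfgF),
               6 * combined_loss(probs$S0[, , 1, 1], G[, , 1, 1], cfg))
  # zero when every level predicts G perfectly
  perfect <- lapply(probs, function(p) G)
  expect_lt(integrated_loss(perfect, G, cfg), 1e-3)
  # level weights rescale their levels
  cfgW <- loss_config(level_weights = c(2, 1, 1, 1, 1, 1))
  expect_equal(integrated_loss(probs, G, cfgW) - integrated_loss(probs, G, cfg),
               combined_loss(probs$S0[, , 1, 1], G[, , 1, 1], cfg))
})

test_that("analytic loss gradients match finite differences", {
  # omega is detached by design, so probe with lambda = 0 (no omega) plus a
  # dedicated fixed-omega check for the weighted term
  set.seed(25)
  n <- 36
  G <- as.numeric(runif(n) < 0.3)
  z <- rnorm(n)
  P <- 1 / (1 + exp(-z))
  cfg0 <- loss_config(lambda = 0)
  g_ana <- dcnet:::combined_loss_grad_logit(P, G, cfg0)
  eps <- 1e-6
  for (i in sample(n, 6)) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (combined_loss(1 / (1 + exp(-zp)), G, cfg0) -
            combined_loss(1 / (1 + exp(-zm)), G, cfg0)) / (2 * eps)
    expect_equal(g_ana[i], num, tolerance = 1e-5)
  }
  # weighted term with omega frozen at its current value
  cfg1 <- loss_config(lambda = 1)
  V <- n
  VP1 <- max(sum(P), 1)
  omega <- (V - VP1) / VP1
  ce_fixed <- function(P) -sum(omega * G * log(P) + (1 - G) * log(1 - P)) / V
  g_ce <- dcnet:::weighted_ce_grad_logit(P, G, cfg1)
  for (i in sample(n, 6)) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (ce_fixed(1 / (1 + exp(-zp))) - ce_fixed(1 / (1 + exp(-zm)))) /
      (2 * eps)
    expect_equal(g_ce[i], num, tolerance = 1e-5)
  }
})
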