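# Supervision: per-level combined loss J = CE + DL, and the integrated
# multi-level sum over S0..Sn.
#
# CE is pixel-wise weighted cross entropy.  With V the pixel count of the
# slice and V_P1 the (soft) predicted tumor area sum(P), the foreground
# weight is omega = (V - V_P1) / V_P1 -- the background/foreground area
# ratio -- so the scarce tumor class is up-weighted:
#   CE = -sum( lambda * omega * G * log P + (1 - G) * log(1 - P) ) / V.
# omega is treated as a constant during differentiation.
#
# DL is the generalized Dice loss with class weights 1/|G1| and 1/|G0|:
#   DL = 1 - 2 (w1 |P1 ∩ G1| + w0 |P0 ∩ G0|) /
#            (w1 (|P1| + |G1|) + w0 (|P0| + |G0|)),
# where P1 = P, P0 = 1 - P (soft), G1 = G, G0 = 1 - G.

#' Loss configuration
#'
#' @param lambda coefficient controlling the influence of the foreground
#'   weight in the cross-entropy term (default 1, the unscaled
#'   background/foreground area ratio; larger values speed early foreground
#'   learning but bias the decision boundary toward over-segmentation).
#' @param epsilon relative stabilizer for divisions (fraction of the
#'   relevant denominator scale).
#' @param level_weights per-level multipliers for J0..Jn (default all 1).
#' @param single_loss if `TRUE`, the integrated loss degenerates to
#'   `(n_levels + 1) * J(S0)` (the single-loss ablation, variant F).
#' @return an object of class `dcnet_loss_config`.
#' @export
loss_config <- function(lambda = 1, epsilon = 1e-6, level_weights = NULL,
                        single_loss = FALSE) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (lambda < 0) stop("lambda must be non-negative")
  structure(list(lambda = lambda, epsilon = epsilon,
                 level_weights = level_weights,
                 single_loss = isTRUE(single_loss)),
            class = "dcnet_loss_config")
}

check_pg <- function(P, G) {
  if (!identical(dim(P), dim(G)) && length(P) != length(G))
    stop("prediction and ground truth shapes differ")
  if (any(P < 0 | P > 1)) stop("probabilities must lie in [0, 1]")
}

#' Pixel-wise weighted cross-entropy loss
#'
#' @param P probability map (values in \[0, 1\]).
#' @param G binary ground-truth mask of the same shape.
#' @param cfg a [loss_config()].
#' @return non-negative scalar.
#' @export
weighted_ce <- function(P, G, cfg = loss_config()) {
  check_pg(P, G)
  V <- length(P)
  VP1 <- vp1_floor(P, G, cfg)
  omega <- (V - VP1) / VP1
  eps <- cfg$epsilon
  Pc <- pmin(pmax(P, eps), 1 - eps)
  -sum(cfg$lambda * omega * G * log(Pc) + (1 - G) * log(1 - Pc)) / V
}

# Soft predicted tumor area, floored at the ground-truth area (and at one
# pixel).  Without the floor, an under-predicting model drives the class
# weight omega = (V - VP1)/VP1 toward 1/epsilon and the foreground gradient
# diverges; with it, omega saturates at the true background/foreground
# ratio, which bounds the summed foreground gradient by ~1 per slice.
vp1_floor <- function(P, G, cfg) {
  max(sum(P), sum(G), cfg$epsilon * length(P), 1)
}

# d(CE)/d(logit), with omega detached; exact where the clamp is inactive.
weighted_ce_grad_logit <- function(P, G, cfg = loss_config()) {
  V <- length(P)
  VP1 <- vp1_floor(P, G, cfg)
  omega <- (V - VP1) / VP1
  ((1 - G) * P - cfg$lambda * omega * G * (1 - P)) / V
}

#' Generalized Dice loss
#'
#' @inheritParams weighted_ce
#' @return scalar in \[0, 1\].
#' @export
generalized_dice_loss <- function(P, G, cfg = loss_config()) {
  check_pg(P, G)
  t <- gdl_terms(P, G, cfg)
  1 - 2 * t$num / t$den
}

gdl_terms <- function(P, G, cfg) {
  V <- length(P)
  g1 <- sum(G); g0 <- V - g1
  w1 <- if (g1 > 0) 1 / g1 else 1 / (cfg$epsilon * V)
  w0 <- if (g0 > 0) 1 / g0 else 1 / (cfg$epsilon * V)
  p1 <- sum(P)
  i1 <- sum(P * G)           # |P1 ∩ G1|
  i0 <- (V - p1) - (g1 - i1) # |P0 ∩ G0| = sum((1-P)(1-G))
  num <- w1 * i1 + w0 * i0
  den <- w1 * (p1 + g1) + w0 * ((V - p1) + g0)
  list(w1 = w1, w0 = w0, num = num, den = den)
}

gdl_grad_logit <- function(P, G, cfg = loss_config()) {
  t <- gdl_terms(P, G, cfg)
  dnum <- t$w1 * G - t$w0 * (1 - G)
  dden <- t$w1 - t$w0
  dP <- -2 * (dnum * t$den - t$num * dden) / t$den^2
  dP * P * (1 - P)
}

#' Combined per-level loss J = CE + DL
#'
#' @inheritParams weighted_ce
#' @return scalar.
#' @export
combined_loss <- function(P, G, cfg = loss_config()) {
  weighted_ce(P, G, cfg) + generalized_dice_loss(P, G, cfg)
}

combined_loss_grad_logit <- function(P, G, cfg = loss_config()) {
  weighted_ce_grad_logit(P, G, cfg) + gdl_grad_logit(P, G, cfg)
}

#' Integrated multi-level loss
#'
#' Sums the combined loss over all supervision levels,
#' `sum_k w_k J(S_k)`; in single-loss mode it is `(n + 1) * J(S0)` so the
#' two training objectives share the same scale.  Losses are averaged over
#' the samples of a batch.
#'
#' @param out a `dcnet_output` from [dcnet_forward()], or a named list of
#'   probability maps `S0..Sn`.
#' @param G ground-truth mask: (H, W) matrix or (H, W, 1, N) tensor
#'   matching the batch.
#' @param cfg a [loss_config()].
#' @param per_level if `TRUE` also return the per-level values.
#' @return scalar loss (or list with `total` and `levels`).
#' @export
integrated_loss <- function(out, G, cfg = loss_config(), per_level = FALSE) {
  probs <- if (inherits(out, "dcnet_output")) out$probs else out
  G <- as_tensor(G)
  n_lv <- length(probs)
  wts <- level_wts(cfg, n_lv)
  N <- dim(as_tensor(probs[[1]]))[4]
  lv <- numeric(n_lv)
  names(lv) <- names(probs)
  if (cfg$single_loss) {
    s0 <- as_tensor(probs[["S0"]])
    j0 <- mean(vapply(seq_len(N), function(i)
      combined_loss(s0[, , 1L, i], G[, , 1L, i], cfg), 0))
    lv["S0"] <- n_lv * j0
    total <- n_lv * j0
  } else {
    for (k in seq_len(n_lv)) {
      p <- as_tensor(probs[[k]])
      lv[k] <- wts[k] * mean(vapply(seq_len(N), function(i)
        combined_loss(p[, , 1L, i], G[, , 1L, i], cfg), 0))
    }
    total <- sum(lv)
  }
  if (per_level) list(total = total, levels = lv) else total
}

level_wts <- function(cfg, n_lv) {
  if (is.null(cfg$level_weights)) rep(1, n_lv)
  else {
    if (length(cfg$level_weights) != n_lv)
      stop("level_weights must have one entry per supervision level")
    cfg$level_weights
  }
}

# Gradients of the batch-mean integrated loss with respect to each level's
# pre-sigmoid logits; returns a named list S0..Sn (NULL entries for levels
# that receive no gradient in single-loss mode).
integrated_loss_grad <- function(out, G, cfg = loss_config()) {
  probs <- out$probs
  G <- as_tensor(G)
  n_lv <- length(probs)
  wts <- level_wts(cfg, n_lv)
  dl <- vector("list", n_lv)
  names(dl) <- names(probs)
  N <- dim(as_tensor(probs[[1]]))[4]
  for (k in seq_len(n_lv)) {
    if (cfg$single_loss && names(probs)[k] != "S0") next
    p <- as_tensor(probs[[k]])
    g <- zeros_like(p)
    w <- if (cfg$single_loss) n_lv else wts[k]
    for (i in seq_len(N))
      g[, , 1L, i] <- w / N *
        combined_loss_grad_logit(p[, , 1L, i], G[, , 1L, i], cfg)
    dl[[k]] <- g
  }
  dl
}
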