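# Training protocol: stochastic gradient descent (lr 1e-4, batch 8),
# three stages of equal length with alternating freezing (stage 1 freezes
# the decoder, stage 2 the encoder, stage 3 nothing), and learning-rate
# decay by 0.1 whenever the validation Dice coefficient has not risen for
# `plateau_patience` epochs.

#' Training configuration
#'
#' @param lr initial learning rate (default 1e-4; reset at each stage).
#' @param batch_size mini-batch size (default 8).
#' @param epochs_per_stage epochs per training stage (the full protocol is
#'   3 x 100; scaled-down runs use fewer).
#' @param n_stages number of stages (default 3).
#' @param plateau_patience epochs without validation-DSC improvement
#'   before the learning rate is multiplied by `plateau_factor`.
#' @param plateau_factor learning-rate decay factor (default 0.1).
#' @param momentum SGD momentum (default 0.9; set 0 for plain SGD).
#' @param clip_norm global gradient-norm ceiling per step (default 10;
#'   `Inf` disables clipping).  The foreground weight of the
#'   cross-entropy term grows like the background/foreground area ratio,
#'   so occasional batches produce gradients orders of magnitude above
#'   typical; clipping keeps the three-stage schedule stable.
#' @param augment apply random rotation/flip/translation to each training
#'   pair, re-sampled every epoch.
#' @param augment_params an [augment_params()] object.
#' @param seed seed for shuffling, augmentation and dropout.
#' @param n_cv_trials cross-validation trials for [cross_validate()].
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, batch_size = 8L, epochs_per_stage = 100L,
                         n_stages = 3L, plateau_patience = 10L,
                         plateau_factor = 0.1, momentum = 0.9,
                         clip_norm = 10, augment = TRUE,
                         augment_params = NULL,
                         seed = 1L, n_cv_trials = 4L) {
  if (lr <= 0) stop("lr must be positive")
  if (plateau_factor <= 0 || plateau_factor >= 1)
    stop("plateau_factor must be in (0, 1)")
  if (plateau_patience < 1) stop("plateau_patience must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs_per_stage = as.integer(epochs_per_stage),
                 n_stages = as.integer(n_stages),
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor, momentum = momentum,
                 clip_norm = clip_norm, augment = isTRUE(augment),
                 augment_params = augment_params,
                 seed = as.integer(seed),
                 n_cv_trials = as.integer(n_cv_trials)),
            class = "train_config")
}

#' Random train/validation split
#'
#' @param scans a list (or vector) of scan identifiers or objects.
#' @param n_train,n_val subset sizes (reference protocol: 30 and 10).
#' @param seed split seed.
#' @return list with disjoint `train` and `val` subsets.
#' @export
split_dataset <- function(scans, n_train = 30L, n_val = 10L, seed = 1L) {
  n <- length(scans)
  if (n < n_train + n_val)
    stop("need at least ", n_train + n_val, " scans, got ", n)
  idx <- with_seed(seed, sample.int(n, n_train + n_val))
  list(train = scans[idx[seq_len(n_train)]],
       val = scans[idx[n_train + seq_len(n_val)]])
}

#' Freeze part of a network
#'
#' Frozen parameters are excluded from optimizer updates (and from
#' [count_parameters()] with `trainable_only = TRUE`); the forward pass is
#' unchanged.  The encoder group comprises the stem, dense blocks,
#' transitions and the pyramid pooling module; the decoder group the skip
#' compressions, decoder levels, heads and the fusion.
#'
#' @param net network.
#' @param part `"encoder"`, `"decoder"`, or `"none"`.
#' @return invisibly, a named logical vector (the freeze mask by module).
#' @export
freeze <- function(net, part = c("none", "encoder", "decoder")) {
  part <- match.arg(part)
  mods <- module_list(net)
  for (m in mods) m$frozen <- (part != "none" && m$group == part)
  net$enc_frozen <- part == "encoder"
  invisible(vapply(mods, function(m) m$frozen, logical(1)))
}

#' One step of the validation-plateau learning-rate rule
#'
#' The validation DSC counts as an improvement only if it strictly exceeds
#' the best seen; after `patience` consecutive non-improving epochs the
#' learning rate is multiplied by `factor` and the counter resets.
#'
#' @param state list with `current_lr`, `best_val_dsc`,
#'   `epochs_since_improvement` (use [plateau_init()] to create).
#' @param val_dsc validation DSC of the finished epoch.
#' @param patience,factor rule parameters.
#' @return the updated state.
#' @export
plateau_step <- function(state, val_dsc, patience = 10L, factor = 0.1) {
  stopifnot(is.finite(val_dsc))
  if (val_dsc > state$best_val_dsc) {
    state$best_val_dsc <- val_dsc
    state$epochs_since_improvement <- 0L
  } else {
    state$epochs_since_improvement <- state$epochs_since_improvement + 1L
    if (state$epochs_since_improvement >= patience) {
      state$current_lr <- state$current_lr * factor
      state$epochs_since_improvement <- 0L
    }
  }
  state
}

#' @rdname plateau_step
#' @param lr initial learning rate.
#' @export
plateau_init <- function(lr) {
  list(current_lr = lr, best_val_dsc = -Inf, epochs_since_improvement = 0L)
}

# Assemble a batch tensor pair from a list of slice_pairs.
batch_tensors <- function(pairs, idx) {
  x <- as_tensor(lapply(pairs[idx], function(p) p$image))
  g <- as_tensor(lapply(pairs[idx], function(p) p$mask))
  list(x = x, g = g)
}

# Mean DSC of the binarized fused prediction over a list of pairs.
validate_dsc <- function(net, pairs, batch_size = 8L) {
  if (!length(pairs)) return(NA_real_)
  scores <- numeric(length(pairs))
  i <- 1L
  while (i <= length(pairs)) {
    idx <- i:min(i + batch_size - 1L, length(pairs))
    b <- batch_tensors(pairs, idx)
    out <- dcnet_forward(net, b$x, training = FALSE)
    pred <- binarize(out$probs$S0)
    for (j in seq_along(idx))
      scores[idx[j]] <- dsc(pred[, , 1L, j], b$g[, , 1L, j])
    i <- i + batch_size
  }
  mean(scores)
}

#' Train one stage of the three-stage protocol
#'
#' Stage 1 freezes the decoder, stage 2 the encoder, stage 3 nothing.
#' Each epoch is one shuffled pass over the (freshly augmented) training
#' pairs; after each epoch the validation DSC drives the plateau rule.
#'
#' @param net network (modified in place).
#' @param data list with `train` and `val` lists of `slice_pair`s.
#' @param cfg a [train_config()].
#' @param stage stage number 1, 2 or 3.
#' @param loss_cfg a [loss_config()].
#' @param epochs number of epochs (defaults to `cfg$epochs_per_stage`).
#' @param verbose print per-epoch progress.
#' @param tracker optional environment; if supplied, the parameter state is
#'   snapshotted into `tracker$best_state` whenever the validation DSC
#'   exceeds `tracker$best_dsc` (epoch-granular checkpointing).
#' @return data frame history: epoch, stage, lr, train_loss, val_dsc.
#' @export
train_stage <- function(net, data, cfg, stage, loss_cfg = loss_config(),
                        epochs = cfg$epochs_per_stage, verbose = FALSE,
                        tracker = NULL) {
  if (!stage %in% 1:3) stop("stage must be 1, 2 or 3")
  if (!length(data$train)) stop("empty training set")
  freeze(net, switch(stage, "1" = "decoder", "2" = "encoder", "3" = "none"))
  # stages are independent training phases: fresh momentum, fresh scheduler
  for (m in module_list(net)) for (p in m$param_names) m[[paste0("v_", p)]] <- NULL
  ap <- if (is.null(cfg$augment_params)) augment_params() else cfg$augment_params
  st <- plateau_init(cfg$lr)
  hist <- vector("list", epochs)
  n <- length(data$train)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_pairs <- if (cfg$augment)
      lapply(data$train, function(p) augment(p, ap)) else data$train
    losses <- c()
    i <- 1L
    while (i <= n) {
      idx <- ord[i:min(i + cfg$batch_size - 1L, n)]
      b <- batch_tensors(ep_pairs, idx)
      out <- dcnet_forward(net, b$x, training = TRUE)
      losses <- c(losses, integrated_loss(out, b$g, loss_cfg))
      dl <- integrated_loss_grad(out, b$g, loss_cfg)
      dcnet_backward(net, dl)
      sgd_step(net, st$current_lr, cfg$momentum, cfg$clip_norm)
      i <- i + cfg$batch_size
    }
    vd <- validate_dsc(net, data$val, cfg$batch_size)
    if (!is.null(tracker) && is.finite(vd) && vd > tracker$best_dsc) {
      tracker$best_dsc <- vd
      tracker$best_state <- get_state(net)
    }
    lr_now <- st$current_lr
    if (is.finite(vd))
      st <- plateau_step(st, vd, cfg$plateau_patience, cfg$plateau_factor)
    hist[[ep]] <- data.frame(epoch = ep, stage = stage, lr = lr_now,
                             train_loss = mean(losses), val_dsc = vd)
    if (verbose)
      message(sprintf("stage %d epoch %3d  lr %.2g  loss %.4f  val DSC %.4f",
                      stage, ep, lr_now, mean(losses), vd))
  }
  do.call(rbind, hist)
}

#' Run the full three-stage training protocol
#'
#' Stages run in order (decoder frozen, encoder frozen, nothing frozen),
#' each for `epochs_per_stage` epochs with the learning rate and plateau
#' scheduler reset at the stage start.  The parameter state with the best
#' validation DSC seen at any epoch is retained.
#'
#' @inheritParams train_stage
#' @return list with `net` (trained, final state), `history` (data frame
#'   over all stages), `best_state` (parameters at the best validation
#'   DSC, loadable with [load_state()]) and `best_val_dsc`.
#' @export
three_stage_train <- function(net, data, cfg, loss_cfg = loss_config(),
                              verbose = FALSE) {
  set.seed(cfg$seed)
  hist <- list()
  tracker <- new.env(parent = emptyenv())
  tracker$best_dsc <- -Inf
  tracker$best_state <- NULL
  for (stage in seq_len(cfg$n_stages)) {
    h <- train_stage(net, data, cfg, min(stage, 3L), loss_cfg,
                     verbose = verbose, tracker = tracker)
    hist[[stage]] <- h
  }
  freeze(net, "none")
  list(net = net, history = do.call(rbind, hist),
       best_state = tracker$best_state, best_val_dsc = tracker$best_dsc)
}

#' Cross-validated training
#'
#' Repeats the split/train/evaluate cycle `n_cv_trials` times with
#' different split seeds and returns the per-trial mean validation DSC --
#' a vector directly usable by [mann_whitney_exact()].
#'
#' @param pairs list of `slice_pair`s.
#' @param net_config a [dcnet_config()].
#' @param cfg a [train_config()].
#' @param n_train,n_val split sizes per trial.
#' @param loss_cfg a [loss_config()].
#' @return numeric vector of length `n_cv_trials`.
#' @export
cross_validate <- function(pairs, net_config, cfg, n_train, n_val,
                           loss_cfg = loss_config()) {
  if (cfg$n_cv_trials < 2L) stop("n_cv_trials must be >= 2")
  vapply(seq_len(cfg$n_cv_trials), function(trial) {
    sp <- split_dataset(pairs, n_train, n_val, seed = cfg$seed + trial)
    net <- dcnet_network(net_config, seed = cfg$seed + 100L + trial)
    cfg_t <- cfg
    cfg_t$seed <- cfg$seed + 200L + trial
    res <- three_stage_train(net, sp, cfg_t, loss_cfg)
    if (!is.null(res$best_state)) load_state(net, res$best_state)
    validate_dsc(net, sp$val, cfg$batch_size)
  }, 0)
}
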