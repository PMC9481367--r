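# Training: deep-supervised binary cross-entropy over the per-layer heads,
# a step learning-rate schedule, and a from-scratch Adam loop with
# gradient masking so frozen (masked) positions stay exactly zero.

#' Training configuration
#'
#' @param epochs number of epochs (default 1000).
#' @param base_learning_rate initial Adam step size (default 0.001).
#' @param lr_period epochs between learning-rate reductions (default 100).
#' @param lr_factor multiplicative decay per period (default 0.5; 1 keeps the
#'   rate constant).
#' @param seed integer seed covering dropout and batch shuffling.
#' @param batch_size `NULL` for full-batch (the default: survival cohorts at
#'   this scale are tiny), otherwise a minibatch size.
#' @param head_loss_weights per-head loss weights (default uniform; use
#'   `c(0,0,0,0,1)` for final-head-only supervision).
#' @param class_weights optional length-2 vector (negative, positive) of
#'   per-class loss weights; `NULL` (default) for unweighted loss,
#'   `"balanced"` for inverse-frequency weights.
#' @param beta1,beta2,adam_eps Adam moment/stability constants (published
#'   defaults).
#' @return class `training_config`.
#' @export
training_config <- function(epochs = 1000L, base_learning_rate = 0.001,
                            lr_period = 100L, lr_factor = 0.5, seed = 1L,
                            batch_size = NULL, head_loss_weights = NULL,
                            class_weights = NULL,
                            beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  if (epochs < 1) config_error("epochs must be >= 1")
  if (base_learning_rate <= 0) config_error("learning rate must be positive")
  if (lr_factor <= 0 || lr_factor > 1) config_error("lr_factor must be in (0, 1]")
  structure(as.list(environment()), class = "training_config")
}

#' Binary cross-entropy loss
#'
#' `L = -(1/N) sum(y log p + (1-y) log(1-p))`, with probabilities clamped to
#' `[eps, 1-eps]`.
#'
#' @param p predicted probabilities; @param y 0/1 labels.
#' @param eps clamp (default 1e-7); @param weights optional per-sample weights
#'   (normalized to mean 1).
#' @return non-negative scalar.
#' @export
bce_loss <- function(p, y, eps = 1e-7, weights = NULL) {
  if (length(p) != length(y)) config_error("p and y length mismatch")
  p <- pmin(pmax(p, eps), 1 - eps)
  w <- if (is.null(weights)) rep(1, length(y)) else weights / mean(weights)
  -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Learning rate at a given epoch
#'
#' Step schedule: `base * factor^floor(epoch / period)` (epoch counted from 0).
#'
#' @param epoch epoch index, 0-based.
#' @param config a [training_config()].
#' @return the learning rate.
#' @export
lr_at_epoch <- function(epoch, config) {
  stopifnot(epoch >= 0)
  config$base_learning_rate * config$lr_factor^(epoch %/% config$lr_period)
}

adam_state <- function(model) {
  z <- function(x) {x[] <- 0; x}
  list(W = lapply(model$layers, function(l) list(m = z(l$W), v = z(l$W))),
       b = lapply(model$layers, function(l) list(m = z(l$b), v = z(l$b))),
       u = lapply(model$heads, function(h) list(m = z(h$u), v = z(h$u))),
       c = lapply(model$heads, function(h) list(m = 0, v = 0)),
       t = 0)
}

adam_step <- function(par, grad, st, lr, cfg, t) {
  st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * grad
  st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * grad^2
  mh <- st$m / (1 - cfg$beta1^t)
  vh <- st$v / (1 - cfg$beta2^t)
  list(par = par - lr * mh / (sqrt(vh) + cfg$adam_eps), st = st)
}

# Head-weighted BCE gradients and full backward pass over one (mini)batch.
backward <- function(model, fw, X, y, hw, sample_w) {
  n <- nrow(X)
  L <- length(model$layers)
  w <- if (is.null(sample_w)) rep(1, n) else sample_w / mean(sample_w)
  gW <- vector("list", L); gb <- vector("list", L)
  gu <- vector("list", L); gc <- numeric(L)
  dH_next <- NULL  # gradient flowing into layer i's activation from layer i+1
  for (i in L:1) {
    h <- fw$hidden[[i]]
    dz <- hw[i] * w * (fw$head_p[, i] - y) / n           # d loss / d head pre-sigmoid
    gu[[i]] <- as.vector(crossprod(h, dz))
    gc[i] <- sum(dz)
    dH <- tcrossprod(dz, model$heads[[i]]$u)             # head path (undropped h)
    if (!is.null(dH_next)) dH <- dH + dH_next
    delta <- dH * (1 - h^2)                              # tanh'
    inp <- if (i == 1) X else {
      hp <- fw$hidden[[i - 1]]
      if (!is.null(fw$drop_masks[[i - 1]])) hp * fw$drop_masks[[i - 1]] else hp
    }
    gW[[i]] <- crossprod(delta, inp) * model$layers[[i]]$M
    gb[[i]] <- colSums(delta)
    if (i > 1) {
      Weff <- model$layers[[i]]$W * model$layers[[i]]$M
      dH_next <- delta %*% Weff
      if (!is.null(fw$drop_masks[[i - 1]])) dH_next <- dH_next * fw$drop_masks[[i - 1]]
    }
  }
  list(W = gW, b = gb, u = gu, c = gc)
}

#' Train a sparse model
#'
#' Deep supervision: BCE is applied to every per-layer head and combined with
#' the head loss weights. Optimized with Adam under the step learning-rate
#' schedule; all randomness (dropout, shuffling) derives from the config
#' seed. Masked weights receive no gradient and remain exactly zero. The
#' best-validation-loss checkpoint is tracked alongside the final model.
#'
#' @param model a `sparse_model` (see [init_model()]).
#' @param features samples x features matrix with sample-id rownames.
#' @param labels named 0/1 vector.
#' @param split list with `train` and `validation` id vectors
#'   (see [split_dataset()]).
#' @param config a [training_config()].
#' @param verbose print per-epoch log lines every `verbose` epochs (0 = quiet).
#' @return list: `model` (final), `best_model` (lowest validation loss),
#'   `history` (data.frame epoch / lr / train_loss / val_loss / val_auc).
#' @export
train_model <- function(model, features, labels, split, config = training_config(),
                        verbose = 0) {
  Xtr <- features[split$train, , drop = FALSE]
  ytr <- labels[split$train]
  Xva <- features[split$validation, , drop = FALSE]
  yva <- labels[split$validation]
  if (nrow(Xtr) == 0 || nrow(Xva) == 0) config_error("empty train or validation partition")
  hw <- config$head_loss_weights %||% rep(1 / length(model$heads), length(model$heads))
  sw <- NULL
  if (identical(config$class_weights, "balanced")) {
    cw <- length(ytr) / (2 * c(sum(ytr == 0), sum(ytr == 1)))
    sw_all <- cw[ytr + 1]
  } else if (!is.null(config$class_weights)) {
    sw_all <- config$class_weights[ytr + 1]
  } else sw_all <- NULL

  set.seed(config$seed)
  st <- adam_state(model)
  hist <- data.frame(epoch = integer(), lr = numeric(), train_loss = numeric(),
                     val_loss = numeric(), val_auc = numeric())
  best <- list(loss = Inf, model = model)
  n <- nrow(Xtr)
  bs <- config$batch_size %||% n
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(epoch, config)
    ord <- if (bs < n) sample(n) else seq_len(n)
    ep_loss <- 0; ep_n <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      fw <- forward(model, Xtr[idx, , drop = FALSE], train_mode = TRUE)
      wb <- if (is.null(sw_all)) NULL else sw_all[idx]
      loss <- sum(vapply(seq_along(model$heads), function(j)
        hw[j] * bce_loss(fw$head_p[, j], ytr[idx], weights = wb), 0))
      if (!is.finite(loss))
        pathnn_error(sprintf("non-finite loss at epoch %d (lr %.2g)", epoch, lr),
                     "pathnn_training_error")
      ep_loss <- ep_loss + loss * length(idx); ep_n <- ep_n + length(idx)
      g <- backward(model, fw, Xtr[idx, , drop = FALSE], ytr[idx], hw, wb)
      st$t <- st$t + 1
      for (i in seq_along(model$layers)) {
        up <- adam_step(model$layers[[i]]$W, g$W[[i]], st$W[[i]], lr, config, st$t)
        model$layers[[i]]$W <- up$par * model$layers[[i]]$M  # keep frozen zeros exact
        st$W[[i]] <- up$st
        up <- adam_step(model$layers[[i]]$b, g$b[[i]], st$b[[i]], lr, config, st$t)
        model$layers[[i]]$b <- up$par; st$b[[i]] <- up$st
        up <- adam_step(model$heads[[i]]$u, g$u[[i]], st$u[[i]], lr, config, st$t)
        model$heads[[i]]$u <- up$par; st$u[[i]] <- up$st
        up <- adam_step(model$heads[[i]]$c, g$c[i], st$c[[i]], lr, config, st$t)
        model$heads[[i]]$c <- up$par; st$c[[i]] <- up$st
      }
    }
    fv <- forward(model, Xva)
    val_loss <- sum(vapply(seq_along(model$heads), function(j)
      hw[j] * bce_loss(fv$head_p[, j], yva), 0))
    val_auc <- if (length(unique(yva)) == 2) auc_rank(yva, fv$combined) else NA_real_
    hist[nrow(hist) + 1L, ] <- list(epoch, lr, ep_loss / ep_n, val_loss, val_auc)
    if (val_loss < best$loss) best <- list(loss = val_loss, model = model)
    if (verbose > 0 && (epoch %% verbose == 0 || epoch == config$epochs - 1))
      message(sprintf("epoch %4d  lr %.2g  train %.4f  val %.4f  val AUC %s",
                      epoch, lr, ep_loss / ep_n, val_loss,
                      ifelse(is.na(val_auc), "NA", sprintf("%.3f", val_auc))))
  }
  list(model = model, best_model = best$model, history = hist)
}
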