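#' Training configuration
#'
#' Defaults: AdamW on a mean binary cross-entropy loss, learning rate
#' 5e-4, batch size 64, a fixed number
#' of epochs with the best-validation-loss checkpoint retained, and an
#' initial decision threshold of 0.5 (to be calibrated after training).
#'
#' `input_side` is the resolution the image branch is trained at: full
#' scenes are block-averaged down to this side before entering the
#' network (global average pooling makes the architecture size-agnostic).
#'
#' @param epochs Number of epochs (default 400).
#' @param learning_rate AdamW step size (default 5e-4).
#' @param batch_size Minibatch size (default 64).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param threshold Initial decision threshold in (0, 1).
#' @param input_side Image side fed to the network (default 32).
#' @param seed RNG seed controlling shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 400L, learning_rate = 5e-4,
                         batch_size = 64L, weight_decay = 0.01,
                         threshold = 0.5, input_side = 32L, seed = 1L) {
  .stop_if(epochs < 1, "epochs must be at least 1")
  .stop_if(learning_rate < 0, "learning_rate must be nonnegative")
  .stop_if(batch_size < 1, "batch_size must be at least 1")
  .stop_if(threshold <= 0 || threshold >= 1, "threshold must lie in (0, 1)")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, threshold = threshold,
                 input_side = as.integer(input_side), seed = as.integer(seed)),
            class = "train_config")
}

#' Mean binary cross-entropy
#'
#' `-mean(t * log(p) + (1 - t) * log(1 - p))` over all slots. Predictions
#' outside (0, 1) are clamped at `1e-7` with a warning.
#'
#' @param predictions Numeric probabilities.
#' @param targets 0/1 (or logical) targets of the same length.
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(predictions, targets) {
  .stop_if(length(predictions) != length(targets),
           "predictions and targets differ in length")
  eps <- 1e-7
  if (any(predictions <= 0 | predictions >= 1)) {
    warning("predictions clamped to (", eps, ", 1 - ", eps, ")")
  }
  p <- pmin(pmax(predictions, eps), 1 - eps)
  t <- as.numeric(targets)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

.adamw_state <- function(params) {
  lapply(params, function(l) list(mw = l$w * 0, vw = l$w * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

.adamw_step <- function(params, grads, state, lr, wd, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$w
    s$vw <- beta2 * s$vw + (1 - beta2) * g$w^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$w <- params[[nm]]$w -
      lr * ((s$mw / b1t) / (sqrt(s$vw / b2t) + eps) + wd * params[[nm]]$w)
    params[[nm]]$b <- params[[nm]]$b -
      lr * (s$mb / b1t) / (sqrt(s$vb / b2t) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# forward in inference mode over index subset, in chunks to bound memory
.predict_idx <- function(model, data, idx, chunk = 256L) {
  out <- matrix(0, model$config$fc_out, length(idx))
  for (start in seq(1, length(idx), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, length(idx))]
    out[, start:(start + length(sel) - 1L)] <-
      nn_forward(model, data$images[, , sel, drop = FALSE],
                 data$details[, sel, drop = FALSE])
  }
  out
}

#' Predict primariness probabilities for prepared data
#'
#' @param model A trained `retina_model`.
#' @param data As produced by [prepare_training_data()].
#' @param idx Sample indices (default all).
#' @return `o_max x length(idx)` probability matrix.
#' @export
predict_scenes <- function(model, data, idx = seq_len(dim(data$images)[3])) {
  .predict_idx(model, data, idx)
}

#' Train the dual-branch classifier
#'
#' Minibatch AdamW on mean binary cross-entropy. Zero-padded slots carry
#' target 0 and stay in the loss. After each epoch the validation loss
#' and all-slot (top-5) validation accuracy at the initial threshold are
#' recorded; the returned model is the best-validation-loss state.
#' Deterministic under the config seed.
#'
#' @param model A `retina_model` (freshly built or warm).
#' @param data As produced by [prepare_training_data()] /
#'   [generate_training_data()]; images must already be at
#'   `config$input_side`.
#' @param split A [split_dataset()] result with non-empty `train` and
#'   `validation` sets.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best state), `log` (one row per epoch:
#'   `epoch`, `train_loss`, `val_loss`, `val_accuracy`, `wall_time`).
#' @export
train_model <- function(model, data, split, config = train_config(),
                        verbose = FALSE) {
  .stop_if(length(split$train) == 0, "empty training partition")
  .stop_if(length(split$validation) == 0, "empty validation partition")
  .stop_if(dim(data$images)[1] != config$input_side,
           "data images are ", dim(data$images)[1], "px but config$input_side is ",
           config$input_side)
  set.seed(config$seed)
  params <- model$params
  state <- .adamw_state(params)
  log <- vector("list", config$epochs)
  best <- list(loss = Inf, params = params)
  t0 <- Sys.time()
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(split$train)
    tr_losses <- c()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      mdl <- model; mdl$params <- params
      fw <- nn_forward(mdl, data$images[, , sel, drop = FALSE],
                       data$details[, sel, drop = FALSE],
                       training = TRUE, keep_cache = TRUE)
      tgt <- data$targets[, sel, drop = FALSE]
      loss <- bce_loss(fw$probs, tgt)
      .stop_if(!is.finite(loss), "non-finite training loss at epoch ", ep)
      tr_losses <- c(tr_losses, loss)
      grads <- nn_backward(mdl, fw$cache, tgt)
      step <- step + 1L
      up <- .adamw_step(params, grads, state, config$learning_rate,
                        config$weight_decay, step)
      params <- up$params
      state <- up$state
    }
    mdl <- model; mdl$params <- params
    vp <- .predict_idx(mdl, data, split$validation)
    vt <- data$targets[, split$validation, drop = FALSE]
    val_loss <- bce_loss(vp, vt)
    val_acc <- mean((vp >= config$threshold) == (vt > 0.5))
    if (val_loss < best$loss) best <- list(loss = val_loss, params = params)
    log[[ep]] <- data.frame(epoch = ep, train_loss = mean(tr_losses),
                            val_loss = val_loss, val_accuracy = val_acc,
                            wall_time = as.numeric(Sys.time() - t0,
                                                   units = "secs"))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      ep, mean(tr_losses), val_loss, val_acc))
    }
  }
  out <- model
  out$params <- best$params
  list(model = out, log = do.call(rbind, log))
}

#' Calibrate the decision threshold on held-out scores
#'
#' Scans the grid `grid_step, 2 * grid_step, ...` (strictly inside (0, 1))
#' and returns the threshold maximizing overall per-slot accuracy of the
#' rule `score >= threshold`; ties are broken toward 0.5 (and then toward
#' the smaller threshold). Optionally maximizes F1 instead.
#'
#' @param scores Numeric probabilities (any shape).
#' @param targets Matching 0/1 targets.
#' @param grid_step Grid resolution (default 0.01).
#' @param objective `"accuracy"` (default) or `"f1"`.
#' @return Scalar threshold in (0, 1).
#' @export
calibrate_threshold <- function(scores, targets, grid_step = 0.01,
                                objective = c("accuracy", "f1")) {
  objective <- match.arg(objective)
  .stop_if(length(scores) == 0, "empty score set")
  s <- as.numeric(scores)
  t <- as.numeric(targets) > 0.5
  grid <- seq(grid_step, 1 - grid_step / 2, by = grid_step)
  obj <- vapply(grid, function(th) {
    pred <- s >= th
    if (objective == "accuracy") {
      mean(pred == t)
    } else {
      tp <- sum(pred & t)
      if (tp == 0) return(0)
      2 * tp / (2 * tp + sum(pred & !t) + sum(!pred & t))
    }
  }, numeric(1))
  best <- obj >= max(obj) - 1e-12
  cand <- grid[best]
  cand[order(abs(cand - 0.5), cand)][1]
}

#' Calibrate the threshold of a trained model on a validation set
#'
#' @param model Trained `retina_model`.
#' @param data Prepared data list.
#' @param idx Validation indices.
#' @inheritParams calibrate_threshold
#' @return Scalar threshold.
#' @export
calibrate_model_threshold <- function(model, data, idx, grid_step = 0.01,
                                      objective = c("accuracy", "f1")) {
  .stop_if(length(idx) == 0, "empty validation set")
  p <- .predict_idx(model, data, idx)
  calibrate_threshold(p, data$targets[, idx, drop = FALSE], grid_step,
                      objective)
}
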