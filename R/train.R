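#' Seed every stochastic component
#'
#' The package draws all randomness (weight initialization, dropout masks,
#' batch shuffling, splitting, synthetic generation) from R's session RNG,
#' so a single seed makes full runs reproducible.
#'
#' @param seed integer.
#' @return invisibly, the seed.
#' @export
set_global_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}

#' Training configuration
#'
#' Defaults follow standard practice for this decoder family: Adam with
#' learning rate 0.001, batch size 32, dropout 0.25, the enhanced
#' cross-entropy loss, early-stopping patience 50 within at most 100
#' stage-1 epochs, and a stage-2 safety cap.
#'
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param max_epochs_stage1 stage-1 epoch cap.
#' @param patience stop stage 1 after this many epochs without a strictly
#'   better validation accuracy (must not exceed `max_epochs_stage1`).
#' @param max_epochs_stage2 stage-2 safety cap (the stage-2 criterion may
#'   never trigger).
#' @param loss `"ece"` or `"ce"`.
#' @param seed integer seed for shuffling/dropout/initialization.
#' @return a `train_config`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 1e-3,
                         max_epochs_stage1 = 100L, patience = 50L,
                         max_epochs_stage2 = 200L,
                         loss = c("ece", "ce"), seed = 1L) {
  loss <- match.arg(loss)
  if (patience > max_epochs_stage1)
    stop("patience must not exceed max_epochs_stage1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = as.numeric(learning_rate),
                 optimizer = "adam",
                 max_epochs_stage1 = as.integer(max_epochs_stage1),
                 patience = as.integer(patience),
                 max_epochs_stage2 = as.integer(max_epochs_stage2),
                 loss = loss, seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gnm
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# forward in eval mode over all trials, chunked to bound memory
glc_predict_logp <- function(model, bands, chunk = 64L) {
  n <- dim(bands$data)[4L]
  out <- matrix(0, model$config$n_classes, n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    out[, idx] <- glc_forward(model,
                              bands$data[, , , idx, drop = FALSE],
                              mode = "eval")$logp
  }
  out
}

# one optimization epoch over shuffled mini-batches; returns updated
# model/opt and the mean training loss
train_epoch <- function(model, Xdata, labels, cfg_tr, opt) {
  n <- dim(Xdata)[4L]
  perm <- sample.int(n)
  tot <- 0
  for (s in seq(1L, n, by = cfg_tr$batch_size)) {
    idx <- perm[s:min(s + cfg_tr$batch_size - 1L, n)]
    Xb <- Xdata[, , , idx, drop = FALSE]
    yb <- labels[idx]
    fw <- glc_forward(model, Xb, mode = "train", keep_cache = TRUE)
    model <- fw$model      # running batch-norm statistics advanced
    loss <- batch_loss(t(fw$logp), yb, cfg_tr$loss)
    if (!is.finite(loss)) stop("non-finite training loss")
    dlogits <- batch_loss_grad(fw$logp, yb, cfg_tr$loss)
    grads <- glc_backward(model, Xb, fw$cache, dlogits)
    step <- adam_step(model$params, grads, opt, cfg_tr$learning_rate)
    model$params <- step$params
    opt <- step$opt
    tot <- tot + loss * length(idx)
  }
  list(model = model, opt = opt, loss = tot / n)
}

eval_loss_acc <- function(model, bands, labels, kind) {
  logp <- glc_predict_logp(model, bands)
  pred <- apply(logp, 2L, which.max) - 1L
  list(loss = batch_loss(t(logp), labels, kind),
       acc = mean(pred == labels))
}

#' Two-stage training with early stopping
#'
#' Stage 1 optimizes the configured loss on the training set; after each
#' epoch the validation accuracy is computed, and training stops when no
#' strict improvement has occurred for `patience` epochs (or at the epoch
#' cap).  The weights of the best-validation-accuracy epoch are then
#' restored.  Stage 2 merges the validation set into the training set and
#' keeps optimizing while monitoring the loss on the former validation
#' trials; it stops as soon as that loss drops below the best stage-1
#' validation loss (or at the stage-2 safety cap).
#'
#' @param model a built [build_glcnet()] model.
#' @param train,val disjoint `epoch_set`s with identical channels.
#' @param config a [train_config()].
#' @param bank the [filter_bank()] producing the model's band input.
#' @return list with `model` (trained) and `history` (a `train_history`:
#'   per-epoch records, `best_val_accuracy`, `best_epoch`,
#'   `stage1_best_val_loss`, `stage2_stopped`).
#' @export
train_two_stage <- function(model, train, val, config = train_config(),
                            bank = filter_bank()) {
  stopifnot(inherits(model, "glcnet_model"), inherits(config, "train_config"))
  if (n_trials(train) < 1L || n_trials(val) < 1L)
    stop("train and val must be non-empty")
  if (n_channels(train) != model$config$n_channels)
    stop("channel count of the data does not match the model")
  set_global_seed(config$seed)
  bt_train <- apply_filterbank(train, bank)
  bt_val <- apply_filterbank(val, bank)
  opt <- adam_init(model$params)
  rec <- list()
  best_acc <- -Inf; best_epoch <- 0L; best_params <- model$params
  best_state <- model$state
  best_val_loss <- Inf
  since_improve <- 0L
  for (ep in seq_len(config$max_epochs_stage1)) {
    step <- train_epoch(model, bt_train$data, train$labels, config, opt)
    model <- step$model; opt <- step$opt
    ev <- eval_loss_acc(model, bt_val, val$labels, config$loss)
    rec[[length(rec) + 1L]] <- data.frame(stage = 1L, epoch = ep,
                                          train_loss = step$loss,
                                          val_loss = ev$loss,
                                          val_accuracy = ev$acc)
    best_val_loss <- min(best_val_loss, ev$loss)
    if (ev$acc > best_acc) {
      best_acc <- ev$acc; best_epoch <- ep
      best_params <- model$params; best_state <- model$state
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$patience) break
    }
  }
  model$params <- best_params
  model$state <- best_state
  # stage 2: merge validation into training, monitor former-val loss
  merged_data <- abind4(bt_train$data, bt_val$data)
  merged_labels <- c(train$labels, val$labels)
  val_idx <- n_trials(train) + seq_len(n_trials(val))
  stage2_stopped <- FALSE
  for (ep in seq_len(config$max_epochs_stage2)) {
    step <- train_epoch(model, merged_data, merged_labels, config, opt)
    model <- step$model; opt <- step$opt
    ev <- eval_loss_acc(model, bt_val, val$labels, config$loss)
    rec[[length(rec) + 1L]] <- data.frame(stage = 2L, epoch = ep,
                                          train_loss = step$loss,
                                          val_loss = ev$loss,
                                          val_accuracy = ev$acc)
    if (ev$loss < best_val_loss) { stage2_stopped <- TRUE; break }
  }
  history <- structure(list(records = do.call(rbind, rec),
                            best_val_accuracy = best_acc,
                            best_epoch = best_epoch,
                            stage1_best_val_loss = best_val_loss,
                            stage2_stopped = stage2_stopped),
                       class = "train_history")
  list(model = model, history = history)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  out <- array(0, c(da[1:3], da[4L] + db[4L]))
  out[, , , seq_len(da[4L])] <- a
  out[, , , da[4L] + seq_len(db[4L])] <- b
  out
}

#' Evaluate a model on a test set
#'
#' Deterministic eval-mode forward pass; predictions are the argmax of the
#' log-probabilities (ties broken toward the lower class index), scored
#' with [metrics_from_confusion()].
#'
#' @param model a `glcnet_model`.
#' @param test an `epoch_set`.
#' @param bank the [filter_bank()] used for training.
#' @return a `metrics_report` with attribute `"predictions"`.
#' @export
evaluate <- function(model, test, bank = filter_bank()) {
  stopifnot(inherits(model, "glcnet_model"))
  if (n_channels(test) != model$config$n_channels)
    stop("channel count of the data does not match the model")
  bt <- apply_filterbank(test, bank)
  logp <- glc_predict_logp(model, bt)
  pred <- apply(logp, 2L, which.max) - 1L
  cm <- confusion(test$labels, pred, model$config$n_classes)
  rep_ <- metrics_from_confusion(cm)
  attr(rep_, "predictions") <- pred
  attr(rep_, "confusion") <- cm
  rep_
}
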