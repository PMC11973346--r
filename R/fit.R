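#' Fit the three-branch decoder to an epoch set
#'
#' The top-level modelling interface.  Given epoched multichannel signals,
#' it (1) splits trials into train/validation/test partitions, (2) builds
#' the sensor graph from the training partition only (phase lag index) or
#' from sensor positions (distance), (3) decomposes epochs with the
#' Chebyshev Type II filter bank, (4) builds and trains the network with
#' the two-stage early-stopping protocol, and (5) scores the held-out test
#' partition.
#'
#' @param epochs an `epoch_set` (see [epoch_set()], [load_epochs()],
#'   [generate_epochs()]).
#' @param bank a [filter_bank()].
#' @param graph `"pli"`, `"distance"`, or an `adjacency_spec`.
#' @param split a [split_spec()].
#' @param config optional [glcnet_config()]; by default one is derived from
#'   the data dimensions (`avg_window = n_times / 5`,
#'   `pool_factor = 10`).
#' @param training a [train_config()].
#' @param ablation optional branch to remove (see [ablate()]).
#' @return an object of class `glcnet`: the trained model, training
#'   history, test metrics, the graph, and all configuration.
#' @seealso [predict.glcnet()], [summary.glcnet()], [plot.glcnet()]
#' @examples
#' \donttest{
#' ep <- generate_epochs(synth_config(n_trials_per_class = 12L, seed = 7L))
#' fit <- glcnet(ep, training = train_config(max_epochs_stage1 = 3L,
#'                                           patience = 3L,
#'                                           max_epochs_stage2 = 1L))
#' print(fit)
#' }
#' @export
glcnet <- function(epochs, bank = filter_bank(), graph = "pli",
                   split = split_spec(), config = NULL,
                   training = train_config(), ablation = NULL) {
  validate_epochs(epochs)
  parts <- split_epochs(epochs, split)
  adj <- resolve_graph(graph, parts$train, bank)
  if (is.null(config))
    config <- default_config_for(epochs, adjacency = adj)
  else if (is.null(config$adjacency)) config$adjacency <- adj
  if (!is.null(ablation)) config <- ablate(config, ablation)
  set_global_seed(training$seed)
  model <- build_glcnet(config)
  fit <- train_two_stage(model, parts$train, parts$val, training, bank)
  metrics <- evaluate(fit$model, parts$test, bank)
  structure(list(model = fit$model, history = fit$history,
                 metrics = metrics, bank = bank, graph = adj,
                 split = parts$indices, config = config,
                 training = training,
                 call = match.call()),
            class = "glcnet")
}

resolve_graph <- function(graph, train, bank) {
  if (inherits(graph, "adjacency_spec")) return(graph)
  switch(graph,
         pli = pli_adjacency(train, bank = bank),
         distance = distance_adjacency(train$positions),
         stop("graph must be 'pli', 'distance' or an adjacency_spec"))
}

# scale the architecture to the data while preserving the shape relations
# (9 bands, pool 10, five fused time steps, 288 spatial filters)
default_config_for <- function(epochs, adjacency, n_bands = 9L) {
  T_ <- n_times(epochs)
  if (T_ %% 10L != 0) stop("n_times must be divisible by the pool factor 10")
  if (T_ %% 50L != 0) stop("n_times must be divisible by 50 (5 fused steps)")
  glcnet_config(n_channels = n_channels(epochs), n_times = T_,
                n_bands = n_bands, n_classes = n_classes(epochs),
                avg_window = T_ %/% 5L, adjacency = adjacency)
}

#' @export
print.glcnet <- function(x, ...) {
  cat("Three-branch graph/spatial/LSTM decoder\n")
  d <- cfg_dims(x$config)
  cat(sprintf("  %d channels, %d samples, %d bands, %d classes; %s graph\n",
              x$config$n_channels, x$config$n_times, x$config$n_bands,
              x$config$n_classes, x$graph$mode))
  if (x$config$drop != "none")
    cat(sprintf("  ablation: %s removed\n", x$config$drop))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x$model), big.mark = ",")))
  h <- x$history
  cat(sprintf("  stage 1: best val accuracy %.3f at epoch %d\n",
              h$best_val_accuracy, h$best_epoch))
  cat(sprintf("  test: accuracy %.3f, macro F1 %.3f, kappa %.3f (n = %d)\n",
              x$metrics$accuracy, x$metrics$f1, x$metrics$kappa,
              x$metrics$n))
  invisible(x)
}

#' @export
summary.glcnet <- function(object, ...) {
  print(object)
  cat("\nParameter registry:\n")
  print(parameter_registry(object$model))
  cat("\nPer-class test metrics:\n")
  print(object$metrics$per_class)
  invisible(object)
}

#' Predict classes or log-probabilities for new epochs
#'
#' @param object a fitted [glcnet()] object.
#' @param newdata an `epoch_set` with the same channel count.
#' @param type `"class"` (default) for 0-based class codes (mapped back to
#'   the training label set), or `"logprob"` for the `[n, Nc]` matrix of
#'   log-probabilities.
#' @param ... unused.
#' @return integer vector or numeric matrix.
#' @export
predict.glcnet <- function(object, newdata, type = c("class", "logprob"),
                           ...) {
  type <- match.arg(type)
  validate_epochs(newdata)
  bt <- apply_filterbank(newdata, object$bank)
  logp <- glc_predict_logp(object$model, bt)
  if (type == "logprob") return(t(logp))
  apply(logp, 2L, which.max) - 1L
}

#' @export
coef.glcnet <- function(object, ...) object$model$params

#' Training-history curves
#'
#' Plots validation accuracy and train/validation loss against epoch, with
#' the stage-1/stage-2 boundary marked.
#'
#' @param x a fitted [glcnet()] object.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.glcnet <- function(x, ...) {
  r <- x$history$records
  ep <- seq_len(nrow(r))
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(ep, r$val_accuracy, type = "l", xlab = "epoch",
       ylab = "validation accuracy", ylim = c(0, 1), ...)
  s2 <- which(r$stage == 2L)[1L]
  if (!is.na(s2)) graphics::abline(v = s2 - 0.5, lty = 3)
  graphics::plot(ep, r$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = range(c(r$train_loss, r$val_loss)), ...)
  graphics::lines(ep, r$val_loss, lty = 2)
  if (!is.na(s2)) graphics::abline(v = s2 - 0.5, lty = 3)
  graphics::legend("topright", legend = c("train", "validation"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' One file holding the trainable weights, the architecture configuration
#' (including the adjacency), the batch-norm running statistics and the
#' training seed, in R's native serialization.
#'
#' @param model a `glcnet_model` or fitted `glcnet` object.
#' @param path file path (conventionally `.rds`).
#' @param seed optional seed to record.
#' @return `save_glcnet`: `path`, invisibly; `load_glcnet`: a
#'   `glcnet_model` with attribute `"seed"`.
#' @export
save_glcnet <- function(model, path, seed = NULL) {
  if (inherits(model, "glcnet")) {
    if (is.null(seed)) seed <- model$training$seed
    model <- model$model
  }
  stopifnot(inherits(model, "glcnet_model"))
  saveRDS(list(params = model$params, config = model$config,
               state = model$state, seed = seed), path)
  invisible(path)
}

#' @rdname save_glcnet
#' @export
load_glcnet <- function(path) {
  x <- readRDS(path)
  restore <- local_rng(0L)   # scratch init below is discarded
  on.exit(restore(), add = TRUE)
  model <- build_glcnet(x$config)
  model$params <- x$params
  model$state <- x$state
  attr(model, "seed") <- x$seed
  model
}

#' @export
print.train_history <- function(x, ...) {
  n1 <- sum(x$records$stage == 1L); n2 <- sum(x$records$stage == 2L)
  cat(sprintf(
    "<train_history> %d stage-1 + %d stage-2 epochs; best val acc %.3f @ %d\n",
    n1, n2, x$best_val_accuracy, x$best_epoch))
  cat(sprintf("  stage-1 best val loss %.4f; stage-2 criterion %s\n",
              x$stage1_best_val_loss,
              if (x$stage2_stopped) "met" else "not met (cap reached)"))
  invisible(x)
}
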