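#' Run a full experiment with optional ablations
#'
#' End-to-end runner: split, train-partition sensor graph, filter bank,
#' two-stage training, test-set evaluation; written out as a report
#' directory containing the metrics JSON, the per-epoch history CSV, the
#' confusion-matrix CSV, and a manifest with every seed and configuration
#' needed to reproduce the run.  When `ablations` is non-empty the
#' experiment is repeated once per removed module and a comparison table
#' (accuracy, kappa, F1 per variant) is written.
#'
#' @param epochs an `epoch_set`, or a path to an HDF5 epoch file, or a
#'   [synth_config()] to generate data on the fly.
#' @param out_dir report directory (created).
#' @param bank,graph,split,config,training forwarded to [glcnet()].
#' @param ablations character vector from `"module1_gcn"`,
#'   `"module2_spatialconv"`, `"module3_lstm"`.
#' @return the report directory path, invisibly; the comparison table (if
#'   any) is also returned as attribute `"comparison"`.
#' @export
run_experiment <- function(epochs, out_dir, bank = filter_bank(),
                           graph = "pli", split = split_spec(),
                           config = NULL, training = train_config(),
                           ablations = character(0)) {
  if (is.character(epochs)) epochs <- load_epochs(epochs)
  if (inherits(epochs, "synth_config")) epochs <- generate_epochs(epochs)
  validate_epochs(epochs)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  variants <- c("full", ablations)
  rows <- list()
  for (v in variants) {
    fit <- glcnet(epochs, bank = bank, graph = graph, split = split,
                  config = config, training = training,
                  ablation = if (v == "full") NULL else v)
    tag <- gsub("[^a-z0-9]+", "_", v)
    m <- fit$metrics
    jsonlite::write_json(
      list(variant = v, accuracy = m$accuracy, f1 = m$f1,
           kappa = m$kappa, n = m$n, per_class = m$per_class),
      file.path(out_dir, sprintf("metrics_%s.json", tag)),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.csv(fit$history$records,
                     file.path(out_dir, sprintf("history_%s.csv", tag)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(attr(m, "confusion"))),
                     file.path(out_dir, sprintf("confusion_%s.csv", tag)))
    rows[[v]] <- data.frame(variant = v, accuracy = m$accuracy,
                            kappa = m$kappa, f1 = m$f1,
                            parameters = count_parameters(fit$model))
    if (v == "full") full_fit <- fit
  }
  comparison <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (length(ablations))
    utils::write.csv(comparison, file.path(out_dir, "ablation_comparison.csv"),
                     row.names = FALSE)
  manifest <- list(
    created = "run_experiment",
    package_version = as.character(utils::packageVersion("glcnet")),
    n_trials = n_trials(epochs), n_channels = n_channels(epochs),
    n_times = n_times(epochs), sfreq = epochs$sfreq,
    split = unclass(split), training = unclass(training),
    bank = list(bands = lapply(full_fit$bank$bands, as.numeric),
                order = full_fit$bank$order, rs_db = full_fit$bank$rs_db,
                zero_phase = full_fit$bank$zero_phase),
    graph_mode = full_fit$graph$mode,
    model = unclass(full_fit$config[setdiff(names(full_fit$config),
                                            "adjacency")]),
    ablations = ablations)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- out_dir
  attr(out, "comparison") <- comparison
  attr(out, "fit") <- full_fit
  invisible(out)
}

#' Export per-trial branch features
#'
#' Extracts eval-mode activations at the fusion stage for external
#' embedding or visualization tools: the graph-branch map (`f1`), the
#' recurrent map (`f2`), the averaged spatial map (`f3`), or their fused
#' sum (`fused`), flattened to one row per trial with a label column.
#'
#' @param model a `glcnet_model` (or a fitted `glcnet` object).
#' @param epochs an `epoch_set`.
#' @param layer one of `"fused"`, `"f1"`, `"f2"`, `"f3"`.
#' @param bank the [filter_bank()] matching the model input.
#' @param file optional CSV path to write.
#' @return data.frame `[n_trials, feature_dim + 1]` (last column `label`).
#' @export
export_features <- function(model, epochs, layer = c("fused", "f1", "f2",
                                                     "f3"),
                            bank = filter_bank(), file = NULL) {
  layer <- match.arg(layer)
  if (inherits(model, "glcnet")) { bank <- model$bank; model <- model$model }
  stopifnot(inherits(model, "glcnet_model"))
  validate_epochs(epochs)
  cfg <- model$config
  d <- cfg_dims(cfg)
  bt <- apply_filterbank(epochs, bank)
  n <- n_trials(epochs)
  feats <- matrix(0, n, d$Fsp * d$Q)
  for (s in seq(1L, n, by = 64L)) {
    idx <- s:min(s + 63L, n)
    fw <- glc_forward(model, bt$data[, , , idx, drop = FALSE],
                      mode = "eval", keep_cache = TRUE)
    Fsum <- array(fw$cache$flat, c(d$Fsp, d$Q, length(idx)))
    x <- switch(layer,
      fused = Fsum,
      f3 = fw$cache$F3,
      f2 = {
        if (!has_branch(cfg, "lstm")) stop("LSTM branch not present")
        F2 <- array(0, c(d$Fsp, d$Q, length(idx)))
        for (q in seq_len(d$Q))
          F2[, q, ] <- model$params$ls_Wr %*%
            matrix(fw$cache$lstm$hs[, , q], cfg$lstm_hidden) +
            model$params$ls_br
        F2
      },
      f1 = {
        if (!has_branch(cfg, "gcn")) stop("GCN branch not present")
        array(fw$cache$gcn$F1a, c(d$Fsp, cfg$gcn_dims[2L], length(idx)))
      })
    feats[idx, seq_len(prod(dim(x)[1:2]))] <-
      t(matrix(x, prod(dim(x)[1:2]), length(idx)))
  }
  if (layer == "f1") feats <- feats[, seq_len(d$Fsp * cfg$gcn_dims[2L]),
                                    drop = FALSE]
  df <- as.data.frame(feats)
  names(df) <- sprintf("%s_%03d", layer, seq_len(ncol(df)))
  df$label <- epochs$labels
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
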