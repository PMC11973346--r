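# Independent oracles used across the suite.  These deliberately use
# naive scalar loops / brute force so they share no code with the package
# implementation they check.

# straight transcription of the LSTM gate recurrence, one scalar at a time
oracle_lstm <- function(params, sequence) {
  H <- nrow(params$w_i); Fx <- ncol(params$w_i); Q <- nrow(sequence)
  h <- numeric(H); cc <- numeric(H)
  out <- matrix(0, Q, H)
  sig <- function(x) 1 / (1 + exp(-x))
  for (t in seq_len(Q)) {
    x <- sequence[t, ]
    for (u in seq_len(H)) {
      zi <- sum(params$w_i[u, ] * x) + sum(params$U_i[u, ] * h) + params$b_i[u]
      zf <- sum(params$w_f[u, ] * x) + sum(params$U_f[u, ] * h) + params$b_f[u]
      zo <- sum(params$w_o[u, ] * x) + sum(params$U_o[u, ] * h) + params$b_o[u]
      zc <- sum(params$w_c[u, ] * x) + sum(params$U_c[u, ] * h) + params$b_c[u]
      out[t, u] <- sig(zo) * tanh(sig(zf) * cc[u] + sig(zi) * tanh(zc))
    }
    # cell/hidden updates must use the *previous* h throughout a step
    cnew <- numeric(H)
    for (u in seq_len(H)) {
      zi <- sum(params$w_i[u, ] * x) + sum(params$U_i[u, ] * h) + params$b_i[u]
      zf <- sum(params$w_f[u, ] * x) + sum(params$U_f[u, ] * h) + params$b_f[u]
      zc <- sum(params$w_c[u, ] * x) + sum(params$U_c[u, ] * h) + params$b_c[u]
      cnew[u] <- sig(zf) * cc[u] + sig(zi) * tanh(zc)
    }
    cc <- cnew
    h <- out[t, ]
  }
  out
}

# triple-loop evaluation of activation(S H W + b)
oracle_gcn_layer <- function(H, S, W, b, activation = "relu") {
  Cn <- nrow(H); Fi <- ncol(H); Fo <- ncol(W)
  out <- matrix(0, Cn, Fo)
  for (i in seq_len(Cn))
    for (o in seq_len(Fo)) {
      acc <- b[o]
      for (j in seq_len(Cn))
        for (k in seq_len(Fi))
          acc <- acc + S[i, j] * H[j, k] * W[k, o]
      out[i, o] <- switch(activation,
                          relu = max(acc, 0),
                          elu = if (acc > 0) acc else exp(acc) - 1,
                          identity = acc)
    }
  out
}

# one-vs-rest metrics straight from definitions
oracle_metrics <- function(cm) {
  total <- sum(cm); K <- nrow(cm)
  acc <- sum(diag(cm)) / total
  f1s <- numeric(K)
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[k] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  pe <- 0
  for (k in seq_len(K)) pe <- pe + sum(cm[k, ]) * sum(cm[, k]) / total^2
  kappa <- if (abs(1 - pe) < 1e-12) 0 else (acc - pe) / (1 - pe)
  list(accuracy = acc, f1 = mean(f1s), kappa = kappa)
}

# brute-force PLI of two single-trial signals from its definition
oracle_pli_pair <- function(x, y) {
  px <- Arg(glcnet:::analytic_signal(matrix(x, ncol = 1)))
  py <- Arg(glcnet:::analytic_signal(matrix(y, ncol = 1)))
  abs(mean(sign(sin(px - py))))
}

subset_epochs_for_test <- function(ep, which) glcnet:::subset_epochs(ep, which)

# random symmetric non-negative adjacency with zero diagonal
random_adjacency <- function(C) {
  A <- matrix(stats::runif(C * C), C)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  custom_adjacency(A / max(A))
}

# small architecture used by network-level tests; biases are nudged off
# zero so no pre-activation sits exactly on a ReLU kink
tiny_model <- function(n_classes = 3L, dropout_p = 0, drop = "none",
                       seed = 3L, randomize_biases = TRUE) {
  set_global_seed(seed)
  cfg <- glcnet_config(n_channels = 4L, n_times = 40L, n_bands = 2L,
                       n_classes = n_classes,
                       temporal_conv_filters = 3L, pool_factor = 4L,
                       gcn_dims = c(6L, 3L), spatial_filters = 8L,
                       spatial_groups = 2L, avg_window = 8L,
                       lstm_hidden = 4L, dropout_p = dropout_p,
                       adjacency = random_adjacency(4L), drop = drop)
  m <- build_glcnet(cfg)
  if (randomize_biases)
    for (nm in grep("_b$|_br$", names(m$params), value = TRUE))
      m$params[[nm]] <- m$params[[nm]] + stats::rnorm(length(m$params[[nm]]), sd = 0.05)
  m
}

tiny_input <- function(model, n = 5L, seed = 9L) {
  cfg <- model$config
  set.seed(seed)
  array(stats::rnorm(cfg$n_bands * cfg$n_channels * cfg$n_times * n),
        c(cfg$n_bands, cfg$n_channels, cfg$n_times, n))
}

# nearest-centroid classifier on log band-power features; an independent
# linear-oracle baseline for separability checks
oracle_linear_accuracy <- function(train, test, bands) {
  feats <- function(ep) {
    bank <- filter_bank(bands)
    bt <- apply_filterbank(ep, bank)
    # log mean power per band x channel
    pw <- apply(bt$data^2, c(1, 2, 4), mean)        # [bands, C, n]
    t(matrix(log(pw + 1e-12), dim(pw)[1] * dim(pw)[2]))
  }
  Xtr <- feats(train); Xte <- feats(test)
  mu <- colMeans(Xtr); sdv <- pmax(apply(Xtr, 2, sd), 1e-8)
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
  cents <- sapply(sort(unique(train$labels)), function(k)
    colMeans(Xtr[train$labels == k, , drop = FALSE]))
  d2 <- as.matrix(stats::dist(rbind(t(cents), Xte)))
  K <- ncol(cents)
  pred <- apply(d2[-(1:K), 1:K, drop = FALSE], 1, which.min) - 1L
  mean(pred == test$labels)
}
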