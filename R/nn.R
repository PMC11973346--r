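# Internal neural-network engine: vectorized forward pass with caching and
# hand-derived backward pass.  Layout conventions:
#   band tensor X   [B, C, T, n]      (band, channel, time, trial)
#   feature maps    [F, ..., n]       trailing trial index
# Convolutions are expressed as matrix products against BLAS; reshapes use
# `dim<-` on freshly allocated intermediates to avoid extra copies.

sigm <- function(x) 1 / (1 + exp(-x))

relu_fwd <- function(x) pmax(x, 0)
elu_fwd <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
elu_bwd <- function(dy, x) dy * exp(pmin(x, 0))

# Batch norm over the first dimension of a [F x N] matrix view.
# mode "train": batch statistics (biased variance), running stats updated.
bn_fwd <- function(xm, g, b, run_mean, run_var, mode, momentum = 0.1,
                   eps = 1e-5) {
  if (mode == "train") {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    istd <- 1 / sqrt(v + eps)
    xhat <- xc * istd
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    istd <- 1 / sqrt(run_var + eps)
    xhat <- (xm - run_mean) * istd
  }
  list(y = xhat * g + b, xhat = xhat, istd = istd,
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dy, cache, g) {
  N <- ncol(dy)
  dg <- rowSums(dy * cache$xhat)
  db <- rowSums(dy)
  dx <- (g * cache$istd) * (dy - db / N - cache$xhat * (dg / N))
  list(dx = dx, dg = dg, db = db)
}

# exponential update of batch-norm running statistics
bn_mix <- function(run, batch, momentum = 0.1) {
  (1 - momentum) * run + momentum * batch
}

# Linear interpolation matrix mapping d_src positions to d_dst positions
# (rows sum to 1); identity when the lengths agree.
interp_matrix <- function(d_src, d_dst) {
  if (d_src == d_dst) return(diag(d_src))
  M <- matrix(0, d_dst, d_src)
  if (d_src == 1L) { M[, 1L] <- 1; return(M) }
  pos <- if (d_dst == 1L) (d_src + 1) / 2
         else seq(1, d_src, length.out = d_dst)
  lo <- pmin(floor(pos), d_src - 1L)
  w <- pos - lo
  for (q in seq_len(d_dst)) {
    M[q, lo[q]] <- 1 - w[q]
    M[q, lo[q] + 1L] <- M[q, lo[q] + 1L] + w[q]
  }
  M
}

# Packed LSTM run shared by the model forward and the exported
# lstm_forward(): gate rows ordered [input; forget; output; candidate].
# X: [features, n, steps] array.  Returns hidden states [H, n, steps] and
# per-step gate caches for backprop.
lstm_run <- function(Wx, Wh, b, X, keep_cache = FALSE) {
  H <- ncol(Wh); n <- dim(X)[2L]; Q <- dim(X)[3L]
  h <- matrix(0, H, n); cc <- matrix(0, H, n)
  hs <- array(0, c(H, n, Q))
  cache <- if (keep_cache) vector("list", Q) else NULL
  idx <- function(k) ((k - 1L) * H + 1L):(k * H)
  for (q in seq_len(Q)) {
    xq <- X[, , q, drop = FALSE]
    dim(xq) <- dim(X)[1:2]
    z <- Wx %*% xq + Wh %*% h + b
    i_g <- sigm(z[idx(1L), , drop = FALSE])
    f_g <- sigm(z[idx(2L), , drop = FALSE])
    o_g <- sigm(z[idx(3L), , drop = FALSE])
    g_g <- tanh(z[idx(4L), , drop = FALSE])
    c_prev <- cc
    cc <- f_g * c_prev + i_g * g_g
    tc <- tanh(cc)
    h_prev <- h
    h <- o_g * tc
    hs[, , q] <- h
    if (keep_cache)
      cache[[q]] <- list(i = i_g, f = f_g, o = o_g, g = g_g,
                         tc = tc, c_prev = c_prev, h_prev = h_prev)
  }
  list(hs = hs, cache = cache)
}

#' Run an LSTM over a sequence
#'
#' Evaluates the standard gated recurrence
#' \deqn{i_t = \sigma(w_i x_t + U_i h_{t-1} + b_i), \quad
#'       f_t = \sigma(w_f x_t + U_f h_{t-1} + b_f),}
#' \deqn{o_t = \sigma(w_o x_t + U_o h_{t-1} + b_o), \quad
#'       \tilde c_t = \tanh(w_c x_t + U_c h_{t-1} + b_c),}
#' \deqn{c_t = f_t \odot c_{t-1} + i_t \odot \tilde c_t, \quad
#'       h_t = o_t \odot \tanh(c_t)}
#' from zero initial state, returning the stacked hidden states.
#'
#' @param params list with input weights `w_i, w_f, w_o, w_c`
#'   (`[hidden, features]`), recurrent weights `U_i, U_f, U_o, U_c`
#'   (`[hidden, hidden]`) and biases `b_i, b_f, b_o, b_c`.
#' @param sequence numeric matrix `[steps, features]`.
#' @return matrix `[steps, hidden]` of hidden states.
#' @export
lstm_forward <- function(params, sequence) {
  sequence <- as.matrix(sequence)
  H <- nrow(as.matrix(params$w_i))
  for (nm in c("w_i", "w_f", "w_o", "w_c"))
    if (ncol(as.matrix(params[[nm]])) != ncol(sequence))
      stop(sprintf("%s has %d columns but sequence has %d features",
                   nm, ncol(as.matrix(params[[nm]])), ncol(sequence)))
  Wx <- rbind(params$w_i, params$w_f, params$w_o, params$w_c)
  Wh <- rbind(params$U_i, params$U_f, params$U_o, params$U_c)
  b <- c(params$b_i, params$b_f, params$b_o, params$b_c)
  X <- array(t(sequence), c(ncol(sequence), 1L, nrow(sequence)))
  out <- lstm_run(Wx, Wh, b, X)
  t(matrix(out$hs, H, nrow(sequence)))
}

# reshaped aperm: permute then set dims (the aperm result is fresh, so the
# dim assignment does not copy)
aperm_dim <- function(x, perm, d) {
  y <- aperm(x, perm)
  dim(y) <- d
  y
}

# ---- forward pass -----------------------------------------------------

# X: [B, C, T, n] band tensor slice.  mode "train" draws dropout masks from
# the current RNG and uses batch statistics; "eval" is deterministic.
glc_forward <- function(model, X, mode = c("eval", "train"),
                        keep_cache = FALSE) {
  mode <- match.arg(mode)
  cfg <- model$config
  d <- cfg_dims(cfg)
  p <- model$params
  st <- model$state
  dims <- dim(X)
  if (length(dims) != 4L || dims[1L] != cfg$n_bands ||
      dims[2L] != cfg$n_channels || dims[3L] != cfg$n_times)
    stop(sprintf(
      "input shape [%s] does not match config [bands=%d, C=%d, T=%d]",
      paste(dims, collapse = ","), cfg$n_bands, cfg$n_channels, cfg$n_times))
  n <- dims[4L]
  B <- cfg$n_bands; C <- cfg$n_channels; T_ <- cfg$n_times
  K0 <- cfg$temporal_conv_kernel; pool <- cfg$pool_factor
  G1 <- cfg$gcn_dims[1L]; G2 <- cfg$gcn_dims[2L]
  Fsp <- d$Fsp; Gf <- d$Gf; Q <- d$Q; P <- d$P; F0 <- d$F0
  keep_p <- 1 - cfg$dropout_p
  cache <- list(mode = mode, n = n)

  # ---- GCN branch (with temporal-conv front end) ----
  F1q <- NULL
  if (has_branch(cfg, "gcn")) {
    padL <- (K0 - 1L) %/% 2L
    Z0 <- cpp_conv_time_fwd(X, p$fe_W, p$fe_b, padL)  # [F0, C*T*n]
    bn0 <- cpp_actnorm_fwd(Z0, p$fe_bn_g, p$fe_bn_b, st$fe_bn_mean,
                           st$fe_bn_var, 1e-5, TRUE, TRUE,
                           mode == "train")
    E0 <- bn0$out
    # max-pool (1, pool) stride pool over time
    dim(E0) <- c(F0, C, T_, n)
    mp <- cpp_maxpool_fwd(E0, pool)
    Ypool <- mp$y
    argp <- mp$arg
    if (mode == "train" && cfg$dropout_p > 0) {
      m0 <- (stats::runif(length(Ypool)) < keep_p) / keep_p
      dim(m0) <- dim(Ypool)
      Ypool_d <- Ypool * m0
    } else { m0 <- NULL; Ypool_d <- Ypool }
    # graph layer 1: S H W1 (S mixes channels, W1 maps P -> G1)
    S <- model$prop$matrix
    H0 <- aperm_dim(Ypool_d, c(2L, 3L, 1L, 4L), c(C, P * F0 * n))
    SH0 <- S %*% H0
    dim(SH0) <- c(C, P, F0, n)
    M1 <- aperm_dim(SH0, c(1L, 3L, 4L, 2L), c(C * F0 * n, P))
    Z1 <- sweep(M1 %*% p$g1_W, 2L, p$g1_b, `+`)
    A1 <- relu_fwd(Z1)                                # [C*F0*n, G1]
    # graph layer 2
    A1a <- A1
    dim(A1a) <- c(C, F0, n, G1)
    H1 <- aperm_dim(A1a, c(1L, 4L, 2L, 3L), c(C, G1 * F0 * n))
    SH1 <- S %*% H1
    dim(SH1) <- c(C, G1, F0, n)
    M2 <- aperm_dim(SH1, c(1L, 3L, 4L, 2L), c(C * F0 * n, G1))
    Z2 <- sweep(M2 %*% p$g2_W, 2L, p$g2_b, `+`)
    A2 <- relu_fwd(Z2)                                # [C*F0*n, G2]
    # channel-aggregating conv (kernel C x 1 over F0 maps) -> Fsp maps
    A2a <- A2
    dim(A2a) <- c(C, F0, n, G2)
    A2m <- aperm_dim(A2a, c(2L, 1L, 4L, 3L), c(F0 * C, G2 * n))
    Zc <- p$gc_W %*% A2m + p$gc_b
    bnc <- cpp_actnorm_fwd(Zc, p$gc_bn_g, p$gc_bn_b, st$gc_bn_mean,
                           st$gc_bn_var, 1e-5, TRUE, TRUE,
                           mode == "train")
    Ec <- bnc$out
    if (mode == "train" && cfg$dropout_p > 0) {
      mc <- (stats::runif(length(Ec)) < keep_p) / keep_p
      dim(mc) <- dim(Ec)
      F1 <- Ec * mc
    } else { mc <- NULL; F1 <- Ec }
    Mi <- interp_matrix(G2, Q)
    F1a <- F1
    dim(F1a) <- c(Fsp, G2, n)
    F1q <- array(0, c(Fsp, Q, n))
    for (q in seq_len(Q)) {
      acc <- matrix(0, Fsp, n)
      for (u in which(Mi[q, ] != 0)) {
        sl <- F1a[, u, , drop = FALSE]
        dim(sl) <- c(Fsp, n)
        acc <- acc + Mi[q, u] * sl
      }
      F1q[, q, ] <- acc
    }
    if (keep_cache)
      cache$gcn <- list(Z0 = Z0, bn0 = bn0,
                        argp = argp, m0 = m0,
                        M1 = M1, Z1 = Z1, M2 = M2, Z2 = Z2, A2m = A2m,
                        Zc = Zc, bnc = bnc, mc = mc, Mi = Mi, F1a = F1a)
    if (mode == "train") {
      st$fe_bn_mean <- bn_mix(st$fe_bn_mean, bn0$mu)
      st$fe_bn_var <- bn_mix(st$fe_bn_var, bn0$var)
      st$gc_bn_mean <- bn_mix(st$gc_bn_mean, bnc$mu)
      st$gc_bn_var <- bn_mix(st$gc_bn_var, bnc$var)
    }
  }

  # ---- spatial-convolution branch ----
  SPz <- array(0, c(Fsp, T_, n))
  for (f in seq_len(B)) {
    rows <- ((f - 1L) * Gf + 1L):(f * Gf)
    Xf <- X[f, , , , drop = FALSE]
    dim(Xf) <- c(C, T_ * n)
    SPz[rows, , ] <- p$sp_W[, , f] %*% Xf
  }
  SPz <- SPz + p$sp_b                                 # recycle along [Fsp]
  dim(SPz) <- c(Fsp, T_ * n)
  bns <- cpp_actnorm_fwd(SPz, p$sp_bn_g, p$sp_bn_b, st$sp_bn_mean,
                         st$sp_bn_var, 1e-5, TRUE, FALSE, mode == "train")
  # non-overlapping temporal averaging: T -> Q windows of length avg_window
  avg <- cfg$avg_window
  SPn <- bns$out
  dim(SPn) <- c(Fsp, avg, Q, n)
  F3 <- colMeans(aperm_dim(SPn, c(2L, 1L, 3L, 4L), c(avg, Fsp * Q * n)))
  dim(F3) <- c(Fsp, Q, n)
  if (mode == "train") {
    st$sp_bn_mean <- bn_mix(st$sp_bn_mean, bns$mu)
    st$sp_bn_var <- bn_mix(st$sp_bn_var, bns$var)
  }
  if (keep_cache) cache$sp <- list(SPz = SPz, bns = bns)

  # ---- LSTM branch ----
  F2 <- NULL
  if (has_branch(cfg, "lstm")) {
    run <- lstm_run(p$ls_Wx, p$ls_Wh, p$ls_b, aperm(F3, c(1L, 3L, 2L)),
                    keep_cache = keep_cache)
    F2 <- array(0, c(Fsp, Q, n))
    for (q in seq_len(Q)) {
      hq <- run$hs[, , q, drop = FALSE]
      dim(hq) <- c(cfg$lstm_hidden, n)
      F2[, q, ] <- p$ls_Wr %*% hq + p$ls_br
    }
    if (keep_cache) cache$lstm <- run
  }

  # ---- fusion and classifier ----
  Fsum <- array(0, c(Fsp, Q, n))
  if (!is.null(F1q)) Fsum <- Fsum + F1q
  if (!is.null(F2)) Fsum <- Fsum + F2
  if (has_branch(cfg, "spatial_fused")) Fsum <- Fsum + F3
  flat <- Fsum
  dim(flat) <- c(Fsp * Q, n)
  logits <- p$cl_W %*% flat + p$cl_b
  if (!all(is.finite(logits)))
    stop("non-finite activations reached the classifier")
  mx <- apply(logits, 2L, max)
  lse <- mx + log(colSums(exp(sweep(logits, 2L, mx, `-`))))
  logp <- sweep(logits, 2L, lse, `-`)
  if (keep_cache) {
    cache$flat <- flat
    cache$logp <- logp
    cache$F3 <- F3
    model$state <- st
  }
  list(logp = logp, cache = if (keep_cache) cache else NULL, model = model)
}
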