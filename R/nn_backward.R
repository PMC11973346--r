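# Hand-derived backward pass mirroring glc_forward().  Takes the gradient
# of the loss w.r.t. the classifier logits and returns gradients for every
# trainable array.  Input gradients are not propagated past the first
# convolution of each branch (the band tensor is data, not a parameter).

glc_backward <- function(model, X, cache, dlogits) {
  cfg <- model$config
  d <- cfg_dims(cfg)
  p <- model$params
  n <- cache$n
  B <- cfg$n_bands; C <- cfg$n_channels; T_ <- cfg$n_times
  K0 <- cfg$temporal_conv_kernel; pool <- cfg$pool_factor
  G1 <- cfg$gcn_dims[1L]; G2 <- cfg$gcn_dims[2L]
  Fsp <- d$Fsp; Gf <- d$Gf; Q <- d$Q; P <- d$P; F0 <- d$F0
  avg <- cfg$avg_window
  g <- list()

  # classifier
  g$cl_W <- tcrossprod(dlogits, cache$flat)
  g$cl_b <- rowSums(dlogits)
  dFsum <- crossprod(p$cl_W, dlogits)
  dim(dFsum) <- c(Fsp, Q, n)

  dF3 <- if (has_branch(cfg, "spatial_fused")) dFsum
         else array(0, c(Fsp, Q, n))

  slice_q <- function(a, q) {
    s <- a[, q, , drop = FALSE]
    dim(s) <- c(dim(a)[1L], n)
    s
  }

  # ---- LSTM branch ----
  if (has_branch(cfg, "lstm")) {
    hs <- cache$lstm$hs
    lc <- cache$lstm$cache
    H <- cfg$lstm_hidden
    g$ls_Wr <- matrix(0, Fsp, H); g$ls_br <- numeric(Fsp)
    g$ls_Wx <- matrix(0, 4L * H, Fsp); g$ls_Wh <- matrix(0, 4L * H, H)
    g$ls_b <- numeric(4L * H)
    dh_next <- matrix(0, H, n); dc_next <- matrix(0, H, n)
    for (q in rev(seq_len(Q))) {
      dF2q <- slice_q(dFsum, q)
      hq <- hs[, , q, drop = FALSE]
      dim(hq) <- c(H, n)
      g$ls_Wr <- g$ls_Wr + tcrossprod(dF2q, hq)
      g$ls_br <- g$ls_br + rowSums(dF2q)
      dh <- crossprod(p$ls_Wr, dF2q) + dh_next
      s <- lc[[q]]
      do_ <- dh * s$tc
      dc <- dh * s$o * (1 - s$tc^2) + dc_next
      di <- dc * s$g; dg_ <- dc * s$i; df <- dc * s$c_prev
      dc_next <- dc * s$f
      dZ <- rbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  do_ * s$o * (1 - s$o),
                  dg_ * (1 - s$g^2))
      g$ls_Wx <- g$ls_Wx + tcrossprod(dZ, slice_q(cache$F3, q))
      g$ls_Wh <- g$ls_Wh + tcrossprod(dZ, s$h_prev)
      g$ls_b <- g$ls_b + rowSums(dZ)
      dF3[, q, ] <- slice_q(dF3, q) + crossprod(p$ls_Wx, dZ)
      dh_next <- crossprod(p$ls_Wh, dZ)
    }
  }

  # ---- spatial branch ----
  # averaging backward: spread each window gradient uniformly over time
  dSPn <- rep(c(dF3), avg) / avg
  dim(dSPn) <- c(Fsp, Q, n, avg)
  dSPn <- aperm_dim(dSPn, c(1L, 4L, 2L, 3L), c(Fsp, T_ * n))
  bnb <- cpp_actnorm_bwd(dSPn, cache$sp$bns$xhat, cache$sp$bns$istd,
                         p$sp_bn_g, p$sp_bn_b, cache$sp$SPz,
                         TRUE, FALSE)
  g$sp_bn_g <- bnb$dg; g$sp_bn_b <- bnb$db
  dSPz <- bnb$dZ
  dim(dSPz) <- c(Fsp, T_, n)
  g$sp_W <- array(0, dim(p$sp_W))
  for (f in seq_len(B)) {
    rows <- ((f - 1L) * Gf + 1L):(f * Gf)
    dSf <- dSPz[rows, , , drop = FALSE]
    dim(dSf) <- c(Gf, T_ * n)
    Xf <- X[f, , , , drop = FALSE]
    dim(Xf) <- c(C, T_ * n)
    g$sp_W[, , f] <- tcrossprod(dSf, Xf)
  }
  dim(dSPz) <- c(Fsp, T_ * n)
  g$sp_b <- rowSums(dSPz)

  # ---- GCN branch ----
  if (has_branch(cfg, "gcn")) {
    gcc <- cache$gcn
    S <- model$prop$matrix
    dF1a <- array(0, c(Fsp, G2, n))
    for (u in seq_len(G2)) {
      acc <- matrix(0, Fsp, n)
      for (q in which(gcc$Mi[, u] != 0))
        acc <- acc + gcc$Mi[q, u] * slice_q(dFsum, q)
      dF1a[, u, ] <- acc
    }
    dF1 <- dF1a
    dim(dF1) <- c(Fsp, G2 * n)
    dEc <- if (!is.null(gcc$mc)) dF1 * gcc$mc else dF1
    bnbc <- cpp_actnorm_bwd(dEc, gcc$bnc$xhat, gcc$bnc$istd,
                            p$gc_bn_g, p$gc_bn_b, gcc$Zc, TRUE, TRUE)
    g$gc_bn_g <- bnbc$dg; g$gc_bn_b <- bnbc$db
    dZc <- bnbc$dZ
    g$gc_W <- tcrossprod(dZc, gcc$A2m)
    g$gc_b <- rowSums(dZc)
    dA2m <- crossprod(p$gc_W, dZc)
    dim(dA2m) <- c(F0, C, G2, n)
    dA2 <- aperm_dim(dA2m, c(2L, 1L, 4L, 3L), c(C * F0 * n, G2))
    dZ2 <- dA2 * (gcc$Z2 > 0)
    g$g2_W <- crossprod(gcc$M2, dZ2)
    g$g2_b <- colSums(dZ2)
    dM2 <- tcrossprod(dZ2, p$g2_W)                 # [C*F0*n, G1]
    dim(dM2) <- c(C, F0, n, G1)
    dSH1 <- aperm_dim(dM2, c(1L, 4L, 2L, 3L), c(C, G1 * F0 * n))
    dH1 <- S %*% dSH1                              # S symmetric
    dim(dH1) <- c(C, G1, F0, n)
    dA1 <- aperm_dim(dH1, c(1L, 3L, 4L, 2L), c(C * F0 * n, G1))
    dZ1 <- dA1 * (gcc$Z1 > 0)
    g$g1_W <- crossprod(gcc$M1, dZ1)
    g$g1_b <- colSums(dZ1)
    dM1 <- tcrossprod(dZ1, p$g1_W)                 # [C*F0*n, P]
    dim(dM1) <- c(C, F0, n, P)
    dSH0 <- aperm_dim(dM1, c(1L, 4L, 2L, 3L), c(C, P * F0 * n))
    dH0 <- S %*% dSH0
    dim(dH0) <- c(C, P, F0, n)
    dYpool <- aperm(dH0, c(3L, 1L, 2L, 4L))        # [F0, C, P, n]
    if (!is.null(gcc$m0)) {
      dYpool <- dYpool * gcc$m0
      dim(dYpool) <- c(F0, C, P, n)
    }
    dE0a <- cpp_maxpool_bwd(dYpool, gcc$argp, pool, T_)
    dim(dE0a) <- c(F0, C * T_ * n)
    bnb0 <- cpp_actnorm_bwd(dE0a, gcc$bn0$xhat, gcc$bn0$istd,
                            p$fe_bn_g, p$fe_bn_b, gcc$Z0, TRUE, TRUE)
    g$fe_bn_g <- bnb0$dg; g$fe_bn_b <- bnb0$db
    dZ0 <- bnb0$dZ
    g$fe_b <- rowSums(dZ0)
    g$fe_W <- cpp_conv_time_wgrad(X, dZ0, F0, K0, (K0 - 1L) %/% 2L)
  }
  g[names(p)]
}
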