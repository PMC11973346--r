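#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of each column of `x` (real
#' matrix, time down the rows): positive frequencies doubled, negative
#' zeroed, DC and Nyquist kept.
#'
#' @param x numeric matrix `[n_times, m]`.
#' @return complex matrix of the same shape.
#' @keywords internal
analytic_signal <- function(x) {
  x <- as.matrix(x)
  T_ <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(T_)
  if (T_ %% 2 == 0) {
    h[1L] <- 1; h[T_ / 2 + 1L] <- 1
    h[2:(T_ / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((T_ + 1L) / 2)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / T_
}

new_adjacency <- function(matrix, mode, self_loops_added = FALSE,
                          channel_names = NULL) {
  structure(list(matrix = matrix, mode = mode,
                 self_loops_added = isTRUE(self_loops_added),
                 channel_names = channel_names),
            class = "adjacency_spec")
}

#' Validate an adjacency specification
#' @param adj an `adjacency_spec`.
#' @return `adj` after checking squareness, symmetry, non-negativity and a
#'   zero diagonal (before self-loop augmentation).
#' @export
validate_adjacency <- function(adj) {
  stopifnot(inherits(adj, "adjacency_spec"))
  A <- adj$matrix
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("adjacency must be square")
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  if (any(A < -1e-12)) stop("adjacency entries must be non-negative")
  if (!adj$self_loops_added && max(abs(diag(A))) > 1e-12)
    stop("adjacency diagonal must be zero before self-loop augmentation")
  if (adj$mode %in% c("pli", "distance") && any(A > 1 + 1e-9))
    stop(sprintf("%s adjacency entries must lie in [0,1]", adj$mode))
  adj
}

#' Phase lag index adjacency from epochs
#'
#' The PLI between channels j and k is the absolute time- and trial-average
#' of the sign of their instantaneous phase difference,
#' `|mean sign(sin(phi_j - phi_k))|`, with phases taken from the analytic
#' signal of each band-passed channel.  It is insensitive to zero-lag
#' (volume-conduction) coupling: identical channels score 0, a constant
#' 90-degree lag scores 1.
#'
#' By default the PLI is averaged over all bands of the filter bank,
#' yielding one shared sensor graph; pass a single `band` for a
#' band-specific graph.  The first and last 5% of samples of each epoch are
#' discarded before averaging to limit edge effects of the analytic signal.
#'
#' @param epochs an `epoch_set` (typically the training partition only, to
#'   avoid leakage into validation/test).
#' @param band optional `c(low, high)` Hz pair; if `NULL`, average over all
#'   bands of `bank`.
#' @param bank a [filter_bank()] supplying the band-pass designs.
#' @return an `adjacency_spec` with mode `"pli"`.
#' @export
pli_adjacency <- function(epochs, band = NULL, bank = filter_bank()) {
  validate_epochs(epochs)
  d <- dim(epochs$data)
  if (d[3L] < 64L) stop("need at least 64 samples for phase estimation")
  sds <- apply(epochs$data, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("channel %d has zero variance", which(sds == 0)[1L]))
  bands <- if (is.null(band)) bank$bands else list(as.numeric(band))
  C <- d[2L]
  acc <- matrix(0, C, C)
  for (b in bands) acc <- acc + pli_one_band(epochs, b, bank)
  A <- acc / length(bands)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  validate_adjacency(new_adjacency(A, "pli",
                                   channel_names = epochs$channel_names))
}

pli_one_band <- function(epochs, band, bank) {
  d <- dim(epochs$data)
  n <- d[1L]; C <- d[2L]; T_ <- d[3L]
  ba <- band_coefficients(bank, band, epochs$sfreq)
  xm <- aperm(epochs$data, c(3L, 2L, 1L))
  dim(xm) <- c(T_, C * n)                    # [T, channel within trial]
  y <- filter_columns(ba, xm, zero_phase = TRUE)
  ph <- Arg(analytic_signal(y))
  keep <- seq.int(max(1L, floor(0.05 * T_) + 1L), T_ - floor(0.05 * T_))
  dim(ph) <- c(T_, C, n)
  ph <- ph[keep, , , drop = FALSE]
  # time-major [samples*trials, C]: column recycling makes the pair loop
  # cheap (sin(a-b) = sin a cos b - cos a sin b)
  phm <- aperm(ph, c(1L, 3L, 2L))
  dim(phm) <- c(length(keep) * n, C)
  sn <- sin(phm); cs <- cos(phm)
  A <- matrix(0, C, C)
  for (j in seq_len(C - 1L)) {
    cols <- (j + 1L):C
    dsin <- sn[, cols, drop = FALSE] * cs[, j] -
      cs[, cols, drop = FALSE] * sn[, j]
    A[cols, j] <- abs(colMeans(sign(dsin)))
  }
  A + t(A)
}

#' Distance-based adjacency from sensor positions
#'
#' Pairwise straight-line distances are min-max normalized to `[0,1]` over
#' the off-diagonal pairs and converted to affinities `A = 1 - d`; the
#' diagonal is forced to zero.  Nearest sensors get weight 1, the farthest
#' pair weight 0.  If all pairwise distances are equal (e.g. two sensors)
#' the normalized distance is defined as 0 and all off-diagonal weights are
#' 1.
#'
#' @param positions numeric matrix `[n_channels, 3]` of sensor coordinates.
#' @return an `adjacency_spec` with mode `"distance"`.
#' @export
distance_adjacency <- function(positions) {
  if (is.null(positions)) stop("sensor positions are required")
  positions <- as.matrix(positions)
  if (anyDuplicated(positions)) stop("duplicate sensor coordinates")
  D <- unname(as.matrix(stats::dist(positions)))
  off <- D[row(D) != col(D)]
  rng <- range(off)
  dn <- if (diff(rng) < 1e-15) matrix(0, nrow(D), ncol(D))
        else (D - rng[1]) / diff(rng)
  A <- 1 - dn
  diag(A) <- 0
  A[A < 0] <- 0
  validate_adjacency(new_adjacency(A, "distance",
                                   channel_names = rownames(positions)))
}

#' Custom adjacency
#'
#' Wraps a user-supplied symmetric non-negative matrix (e.g. a precomputed
#' geodesic distance affinity) as an adjacency specification.
#'
#' @param matrix square symmetric non-negative matrix with zero diagonal.
#' @param channel_names optional channel names.
#' @return an `adjacency_spec` with mode `"custom"`.
#' @export
custom_adjacency <- function(matrix, channel_names = NULL) {
  validate_adjacency(new_adjacency(as.matrix(matrix), "custom",
                                   channel_names = channel_names))
}

#' Read / write an adjacency matrix as CSV
#'
#' The CSV is the dense `n x n` matrix with a header row of channel names.
#'
#' @param adj an `adjacency_spec`.
#' @param path CSV file path.
#' @param mode adjacency mode to assign on read.
#' @return `write_adjacency`: `path` invisibly; `read_adjacency`: an
#'   `adjacency_spec`.
#' @export
write_adjacency <- function(adj, path) {
  validate_adjacency(adj)
  A <- adj$matrix
  colnames(A) <- adj$channel_names %||%
    sprintf("ch%03d", seq_len(ncol(A)))
  utils::write.csv(A, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path, mode = "custom") {
  df <- utils::read.csv(path, check.names = FALSE)
  A <- as.matrix(df)
  rownames(A) <- NULL
  validate_adjacency(new_adjacency(unname(A), mode,
                                   channel_names = colnames(df)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Symmetric propagation matrix of a sensor graph
#'
#' Augments the adjacency with self loops and normalizes it symmetrically:
#' `S = D^{-1/2} (A + I) D^{-1/2}` with `D_ii = sum_j (A + I)_ij`.  The
#' result is symmetric with spectral radius at most 1, which keeps repeated
#' graph convolutions numerically stable.
#'
#' @param adj an `adjacency_spec`.
#' @return a `propagation_matrix` (list with `matrix` and `normalization`).
#' @export
normalize_adjacency <- function(adj) {
  validate_adjacency(adj)
  A <- adj$matrix + diag(nrow(adj$matrix))
  dinv <- 1 / sqrt(rowSums(A))
  S <- A * tcrossprod(dinv)
  structure(list(matrix = S, normalization = "sym"),
            class = "propagation_matrix")
}

#' One graph-convolution layer
#'
#' Computes `activation(S %*% H %*% W + b)` where `S` is the normalized
#' propagation matrix: node features are mixed along the sensor graph, then
#' linearly mapped and passed through the nonlinearity.
#'
#' @param node_features matrix `[n_channels, in_features]`.
#' @param prop a `propagation_matrix` from [normalize_adjacency()].
#' @param weight matrix `[in_features, out_features]`.
#' @param bias vector of length `out_features` (default zeros).
#' @param activation one of `"relu"`, `"elu"`, `"identity"`.
#' @return matrix `[n_channels, out_features]`.
#' @export
gcn_layer_forward <- function(node_features, prop, weight, bias = NULL,
                              activation = c("relu", "elu", "identity")) {
  activation <- match.arg(activation)
  H <- as.matrix(node_features)
  S <- prop$matrix
  if (nrow(H) != nrow(S))
    stop(sprintf("node_features has %d rows but graph has %d nodes",
                 nrow(H), nrow(S)))
  if (ncol(H) != nrow(weight))
    stop(sprintf("expected %d input features, got %d", nrow(weight), ncol(H)))
  if (is.null(bias)) bias <- numeric(ncol(weight))
  Z <- S %*% H %*% weight
  Z <- sweep(Z, 2L, bias, `+`)
  switch(activation,
         relu = pmax(Z, 0),
         elu = ifelse(Z > 0, Z, exp(pmin(Z, 0)) - 1),
         identity = Z)
}
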