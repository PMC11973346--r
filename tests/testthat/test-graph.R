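make_lagged_epochs <- function(lag_rad, sf = 250, dur = 4, f0 = 10,
                               noise = 0) {
  tt <- (0:(sf * dur - 1)) / sf
  x <- sin(2 * pi * f0 * tt)
  y <- sin(2 * pi * f0 * tt - lag_rad)
  set.seed(1)
  d <- array(0, c(1, 2, length(tt)))
  d[1, 1, ] <- x + noise * rnorm(length(tt))
  d[1, 2, ] <- y + noise * rnorm(length(tt))
  epoch_set(d, 0L, sf)
}

test_that("PLI matches its phase-difference ground truth", {
  # constant 90-degree lag: sign of the phase difference never changes
  ep <- make_lagged_epochs(pi / 2)
  A <- pli_adjacency(ep, band = c(8, 12))$matrix
  expect_gte(A[1, 2], 0.99)
  expect_identical(diag(A), c(0, 0))
  # identical channels: phase difference identically zero, sign 0
  tt <- (0:999) / 250
  x <- sin(2 * pi * 10 * tt) + 0.1 * rnorm(1000)
  ds <- array(0, c(1, 2, 1000)); ds[1, 1, ] <- x; ds[1, 2, ] <- x
  same <- epoch_set(ds, 0L, 250)
  expect_lt(pli_adjacency(same, band = c(8, 12))$matrix[1, 2], 1e-12)
})

test_that("PLI agrees with the brute-force single-pair oracle", {
  ep <- make_lagged_epochs(pi / 3, noise = 0.2)
  band <- c(8, 12)
  A <- pli_adjacency(ep, band = band)$matrix
  bank <- filter_bank()
  ba <- glcnet:::band_coefficients(bank, band, ep$sfreq)
  xs <- glcnet:::filter_columns(ba, cbind(ep$data[1, 1, ], ep$data[1, 2, ]))
  T_ <- dim(ep$data)[3]
  keep <- (floor(0.05 * T_) + 1):(T_ - floor(0.05 * T_))
  expect_equal(A[2, 1],
               oracle_pli_pair(xs[, 2][keep], xs[, 1][keep]),
               tolerance = 1e-10)
})

test_that("independent noise stays below the Monte-Carlo null quantile", {
  sf <- 250; T_ <- sf * 60
  set.seed(42)
  d <- array(rnorm(1 * 2 * T_), c(1, 2, T_))
  ep <- epoch_set(d, 0L, sf)
  pli <- pli_adjacency(ep, band = c(8, 12))$matrix[1, 2]
  # Monte-Carlo null: |mean sign| for independent band-limited pairs at
  # this sample count, computed with the brute-force oracle
  ba <- glcnet:::band_coefficients(filter_bank(), c(8, 12), sf)
  null <- replicate(40, {
    z <- glcnet:::filter_columns(ba, matrix(rnorm(2 * T_), T_))
    oracle_pli_pair(z[, 1], z[, 2])
  })
  expect_lt(pli, stats::quantile(null, 0.95) + 0.02)
  expect_lte(pli, 0.1)
})

test_that("PLI output is a valid adjacency for arbitrary inputs", {
  set.seed(8)
  ep <- epoch_set(array(rnorm(3 * 4 * 200), c(3, 4, 200)), c(0, 1, 0), 250)
  adj <- pli_adjacency(ep)          # averaged over all 9 bands
  A <- adj$matrix
  expect_true(all(A >= 0 & A <= 1))
  expect_equal(A, t(A))
  expect_identical(diag(A), rep(0, 4))
  const <- ep; const$data[, 2, ] <- 0
  expect_error(pli_adjacency(const), "channel 2")
})

test_that("distance adjacency min-max normalizes to [0,1] affinities", {
  # 3 collinear equally spaced sensors: nearest pairs 1, farthest 0
  pos <- cbind(c(0, 1, 2), 0, 0)
  A <- distance_adjacency(pos)$matrix
  expect_equal(A[1, 2], 1)
  expect_equal(A[2, 3], 1)
  expect_equal(A[1, 3], 0)
  expect_identical(diag(A), rep(0, 3))
  # 2 sensors: degenerate min-max defines d = 0, A = 1
  A2 <- distance_adjacency(cbind(c(0, 1), 0, 0))$matrix
  expect_equal(A2[1, 2], 1)
  expect_error(distance_adjacency(NULL), "positions")
  expect_error(distance_adjacency(rbind(c(0, 0, 0), c(0, 0, 0))),
               "duplicate")
})

test_that("adjacency normalization reproduces hand-computed values", {
  # no edges: propagation matrix is the identity
  Z <- custom_adjacency(matrix(0, 3, 3))
  expect_equal(normalize_adjacency(Z)$matrix, diag(3))
  # 3-node path graph with unit weights: degrees of A+I are (2,3,2)
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  S <- normalize_adjacency(custom_adjacency(A))$matrix
  expect_equal(diag(S), c(1 / 2, 1 / 3, 1 / 2))
  expect_equal(S[1, 2], 1 / sqrt(6))
  expect_equal(S[2, 3], 1 / sqrt(6))
  expect_equal(S[1, 3], 0)
})

test_that("normalized propagation has unit spectral bound", {
  set.seed(5)
  for (rep in 1:100) {
    C <- sample(2:20, 1)
    S <- normalize_adjacency(random_adjacency(C))$matrix
    expect_equal(S, t(S), tolerance = 1e-12)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-6)
  }
})

test_that("adjacency CSV round-trips", {
  adj <- random_adjacency(5)
  f <- tempfile(fileext = ".csv")
  write_adjacency(adj, f)
  back <- read_adjacency(f)
  expect_equal(back$matrix, adj$matrix, tolerance = 1e-12)
  unlink(f)
})

test_that("graph layer matches the triple-loop oracle and symmetries", {
  set.seed(11)
  S <- normalize_adjacency(random_adjacency(4))
  H <- matrix(rnorm(4 * 3), 4)
  W <- matrix(rnorm(3 * 2), 3)
  b <- rnorm(2)
  for (act in c("relu", "elu", "identity")) {
    got <- gcn_layer_forward(H, S, W, b, activation = act)
    expect_equal(got, oracle_gcn_layer(H, S$matrix, W, b, act),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # identity propagation, identity activation reduces to a linear map
  id <- normalize_adjacency(custom_adjacency(matrix(0, 4, 4)))
  expect_equal(gcn_layer_forward(H, id, W, activation = "identity"),
               H %*% W, ignore_attr = TRUE)
  # complete graph with identical feature rows: all output rows identical
  K <- custom_adjacency(matrix(1, 4, 4) - diag(4))
  Hsame <- matrix(rep(rnorm(3), each = 4), 4)
  out <- gcn_layer_forward(Hsame, normalize_adjacency(K), W, b)
  expect_lt(max(abs(sweep(out, 2, out[1, ]))), 1e-12)
  expect_error(gcn_layer_forward(H, S, matrix(0, 5, 2)), "input features")
})

test_that("graph layer is permutation equivariant", {
  set.seed(12)
  C <- 6
  adj <- random_adjacency(C)
  H <- matrix(rnorm(C * 4), C)
  W <- matrix(rnorm(4 * 3), 4)
  b <- rnorm(3)
  perm <- sample(C)
  Pm <- diag(C)[perm, ]
  out <- gcn_layer_forward(H, normalize_adjacency(adj), W, b)
  adj_p <- custom_adjacency(adj$matrix[perm, perm])
  out_p <- gcn_layer_forward(H[perm, ], normalize_adjacency(adj_p), W, b)
  expect_equal(out_p, Pm %*% out, tolerance = 1e-10, ignore_attr = TRUE)
})
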