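test_that("cross-entropy matches its closed form on spot values", {
  expect_equal(cross_entropy(c(1, 0, 0, 0), c(1, 0, 0, 0)), 0)
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), -log(0.5),
               tolerance = 1e-6)
  expect_equal(cross_entropy(rep(0.25, 4), rep(0.25, 4)), log(4),
               tolerance = 1e-6)
  expect_error(cross_entropy(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
  expect_error(cross_entropy(c(1, 0), c(1, 0, 0)), "length")
})

test_that("enhanced cross-entropy down-weights easy samples", {
  expect_equal(enhanced_cross_entropy(c(1, 0), c(1, 0)), 0)
  expect_equal(enhanced_cross_entropy(c(1, 0), c(0.5, 0.5)),
               0.25 * (-log(0.5)), tolerance = 1e-6)   # 0.1733
  expect_equal(enhanced_cross_entropy(c(1, 0), c(0.9, 0.1)),
               0.01 * (-log(0.9)), tolerance = 1e-6)   # 0.001054
  # the confident-correct case is re-weighted far below plain CE
  expect_lt(enhanced_cross_entropy(c(1, 0), c(0.9, 0.1)) /
              cross_entropy(c(1, 0), c(0.9, 0.1)), 0.011)
})

test_that("ECE <= CE for one-hot targets over random predictions", {
  set.seed(2)
  for (rep in 1:1000) {
    K <- sample(2:6, 1)
    q <- stats::runif(K); q <- q / sum(q)
    p <- numeric(K); p[sample(K, 1)] <- 1
    ce <- cross_entropy(p, q)
    ece <- enhanced_cross_entropy(p, q)
    expect_lte(ece, ce + 1e-12)
    expect_gte(ece, 0)
  }
})

test_that("batch loss averages the per-trial closed forms", {
  lp <- log(rbind(c(0.5, 0.5), c(0.9, 0.1)))
  expect_equal(batch_loss(lp, c(0L, 0L), "ece"),
               (0.25 * -log(0.5) + 0.01 * -log(0.9)) / 2,
               tolerance = 1e-6)                       # 0.0872
  expect_equal(batch_loss(log(matrix(c(1, 1e-12), 1)), 0L, "ce"), 0,
               tolerance = 1e-9)
  expect_equal(batch_loss(log(matrix(c(1, 1e-12), 1)), 0L, "ece"), 0,
               tolerance = 1e-9)
  set.seed(3)
  lp <- t(apply(matrix(rnorm(40), 10), 1, function(z) z - max(z) -
                  log(sum(exp(z - max(z))))))
  y <- sample(0:3, 10, replace = TRUE)
  expect_lte(batch_loss(lp, y, "ece"), batch_loss(lp, y, "ce"))
  expect_error(batch_loss(lp, c(y[-10], 7L)), "trial 10")
})

test_that("loss gradient on logits matches finite differences", {
  set.seed(4)
  z <- matrix(rnorm(12), 4)                 # [Nc=4, n=3] raw scores
  y <- c(0L, 2L, 3L)
  logsoft <- function(z) sweep(z, 2, apply(z, 2, function(v)
    max(v) + log(sum(exp(v - max(v))))), "-")
  for (kind in c("ce", "ece")) {
    g <- glcnet:::batch_loss_grad(logsoft(z), y, kind)
    for (i in seq_along(z)) {
      h <- 1e-6
      zp <- z; zp[i] <- zp[i] + h
      zm <- z; zm[i] <- zm[i] - h
      num <- (batch_loss(t(logsoft(zp)), y, kind) -
                batch_loss(t(logsoft(zm)), y, kind)) / (2 * h)
      expect_equal(g[i], num, tolerance = 1e-5)
    }
  }
})

test_that("confusion counts by true row and predicted column", {
  cm <- confusion(0:3, 0:3, 4)
  expect_identical(sum(diag(cm)), 4L)
  expect_identical(sum(cm), 4L)
  cm2 <- confusion(c(0, 0, 1), c(0, 1, 1), 2)
  expect_identical(cm2[1, 1], 1L)
  expect_identical(cm2[1, 2], 1L)
  expect_identical(cm2[2, 2], 1L)
  set.seed(5)
  y <- sample(0:2, 50, replace = TRUE)
  p <- sample(0:2, 50, replace = TRUE)
  cm3 <- confusion(y, p, 3)
  expect_identical(as.integer(rowSums(cm3)),
                   as.integer(table(factor(y, levels = 0:2))))
  expect_error(confusion(0:2, 0:1, 3), "length")
  expect_error(confusion(c(0, 3), c(0, 0), 3), "range")
})

test_that("metrics reproduce the published formulas on known cases", {
  perfect <- confusion(rep(0:3, 5), rep(0:3, 5), 4)
  r <- metrics_from_confusion(perfect)
  expect_equal(r$accuracy, 1)
  expect_equal(r$f1, 1)
  expect_equal(r$kappa, 1)
  # binary case: TP=8, FN=4, FP=2, TN=6 (positive class = 1)
  cm <- matrix(c(6L, 4L, 2L, 8L), 2)       # rows true, cols pred
  rb <- metrics_from_confusion(structure(cm, class = c("confusion_matrix",
                                                       "matrix")))
  expect_equal(rb$per_class$recall[2], 2 / 3, tolerance = 1e-4)
  expect_equal(rb$per_class$precision[2], 0.8, tolerance = 1e-4)
  expect_equal(rb$per_class$f1[2], 0.7273, tolerance = 1e-4)
  # all predictions one class on balanced labels: chance-corrected to 0
  all0 <- confusion(rep(0:3, each = 10), rep(0L, 40), 4)
  r0 <- metrics_from_confusion(all0)
  expect_equal(r0$accuracy, 0.25)
  expect_equal(r0$kappa, 0)
})

test_that("metrics agree with brute force and kappa <= accuracy", {
  set.seed(6)
  for (rep in 1:100) {
    K <- sample(2:6, 1)
    cm <- matrix(rpois(K * K, 3), K)
    if (sum(cm) == 0) cm[1, 1] <- 1
    cm <- structure(cm, class = c("confusion_matrix", "matrix"))
    got <- metrics_from_confusion(cm)
    want <- oracle_metrics(unclass(cm))
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_equal(got$kappa, want$kappa, tolerance = 1e-12)
    pe <- sum(rowSums(unclass(cm)) * colSums(unclass(cm))) / sum(cm)^2
    if (pe > 0 && pe < 1) expect_lte(got$kappa, got$accuracy + 1e-12)
    expect_gte(got$kappa, -1)
    expect_lte(got$kappa, 1)
  }
  expect_error(metrics_from_confusion(structure(matrix(0L, 2, 2),
                                                class = "confusion_matrix")),
               "empty")
})
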