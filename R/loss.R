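EPS_Q <- 1e-12

check_dist <- function(x, name) {
  if (any(x < -1e-9)) stop(sprintf("%s has negative entries", name))
  if (abs(sum(x) - 1) > 1e-6) stop(sprintf("%s does not sum to 1", name))
  pmin(pmax(x, 0), 1)
}

#' Cross-entropy between a true and a predicted distribution
#'
#' `H(p, q) = -sum_x p(x) log q(x)` with natural logarithms; `q` is clipped
#' at 1e-12 before the log.  Zero exactly when `q` puts all mass on the
#' true class.
#'
#' @param p true-label distribution (one-hot in practice).
#' @param q predicted distribution; same length as `p`.
#' @return non-negative scalar.
#' @export
cross_entropy <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  p <- check_dist(p, "p"); q <- check_dist(q, "q")
  -sum(p * log(pmax(q, EPS_Q)))
}

#' Enhanced (focal-style) cross-entropy
#'
#' `H(p, q) = -sum_x (1 - q(x))^2 p(x) log q(x)`: confident correct
#' predictions are down-weighted by the squared complement of the predicted
#' probability, so easy samples contribute little and difficult samples
#' dominate the loss.  For one-hot `p` this is never larger than the plain
#' cross-entropy.
#'
#' @inheritParams cross_entropy
#' @return non-negative scalar.
#' @export
enhanced_cross_entropy <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  p <- check_dist(p, "p"); q <- check_dist(q, "q")
  -sum((1 - q)^2 * p * log(pmax(q, EPS_Q)))
}

#' Mean loss of a batch of log-probability rows
#'
#' @param logits numeric matrix `[n, Nc]` of log-probabilities (rows
#'   log-sum-exp to 0).
#' @param labels integer vector in `0..Nc-1`.
#' @param kind `"ce"` or `"ece"`.
#' @return mean per-trial loss.
#' @export
batch_loss <- function(logits, labels, kind = c("ece", "ce")) {
  kind <- match.arg(kind)
  logits <- as.matrix(logits)
  n <- nrow(logits); Nc <- ncol(logits)
  labels <- as.integer(labels)
  bad <- which(labels < 0L | labels >= Nc)
  if (length(bad))
    stop(sprintf("label out of range 0..%d at trial %d", Nc - 1L, bad[1L]))
  lq <- logits[cbind(seq_len(n), labels + 1L)]
  lq <- pmax(lq, log(EPS_Q))
  qt <- exp(lq)
  per <- if (kind == "ce") -lq else (1 - qt)^2 * (-lq)
  mean(per)
}

# Gradient of the mean batch loss w.r.t. the classifier logits, for
# column-major log-probabilities logp [Nc, n] produced by glc_forward().
# For CE: (q - onehot)/n.  For ECE with one-hot p:
#   dL/dq_t = 2 (1 - q_t) log q_t - (1 - q_t)^2 / q_t
#   dL/dz_j = dL/dq_t * q_t * (1[j = t] - q_j)
batch_loss_grad <- function(logp, labels, kind = c("ece", "ce")) {
  kind <- match.arg(kind)
  Nc <- nrow(logp); n <- ncol(logp)
  qm <- exp(logp)
  oh <- matrix(0, Nc, n)
  oh[cbind(labels + 1L, seq_len(n))] <- 1
  if (kind == "ce") return((qm - oh) / n)
  qt <- qm[cbind(labels + 1L, seq_len(n))]
  qt <- pmax(qt, EPS_Q)
  gq <- 2 * (1 - qt) * log(qt) - (1 - qt)^2 / qt
  dz <- sweep(oh - qm, 2L, gq * qt, `*`)
  dz / n
}

#' Confusion matrix
#'
#' @param labels,predictions integer vectors in `0..Nc-1`, equal length.
#' @param n_classes number of classes Nc.
#' @return a `confusion_matrix`: integer `Nc x Nc` matrix, rows = true
#'   class, columns = predicted class.
#' @export
confusion <- function(labels, predictions, n_classes) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (length(labels) != length(predictions))
    stop("labels and predictions must have the same length")
  if (any(labels < 0L | labels >= n_classes) ||
      any(predictions < 0L | predictions >= n_classes))
    stop("values out of range 0..Nc-1")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1L),
                               pred = 0:(n_classes - 1L)))
  for (i in seq_along(labels))
    cm[labels[i] + 1L, predictions[i] + 1L] <-
      cm[labels[i] + 1L, predictions[i] + 1L] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total; precision and recall are one-vs-
#' rest per class; F1 is the macro (unweighted) average of per-class
#' `2 P R / (P + R)`; Cohen's kappa is `(acc - p_e) / (1 - p_e)` with
#' chance agreement `p_e = sum_k row_k col_k / total^2` (kappa defined as 0
#' when `p_e = 1`).  Per-class precision/recall with an empty denominator
#' are defined as 0.
#'
#' @param cm a [confusion()] matrix.
#' @return a `metrics_report` list: `accuracy`, `f1`, `kappa`, `per_class`
#'   (data.frame with precision/recall/f1), `n`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  Nc <- nrow(cm)
  acc <- sum(diag(cm)) / total
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1c <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (abs(1 - pe) < 1e-12) 0 else (acc - pe) / (1 - pe)
  structure(list(accuracy = acc,
                 f1 = mean(f1c),
                 kappa = kappa,
                 per_class = data.frame(class = 0:(Nc - 1L),
                                        precision = prec, recall = rec,
                                        f1 = f1c, row.names = NULL),
                 n = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro F1 %.4f | kappa %.4f | n = %d\n",
              x$accuracy, x$f1, x$kappa, x$n))
  invisible(x)
}
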