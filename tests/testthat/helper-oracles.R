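# Independent brute-force oracles used to check the fast implementations.

# Mann-Whitney AUC by exhaustive pair counting.
oracle_auc_paircount <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Naive O(n^2) kernel-matrix DeLong computation.
oracle_delong_naive <- function(sa, sb, labels) {
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  comp <- function(s) {
    pos <- s[labels == 1]
    neg <- s[labels == 0]
    K <- outer(pos, neg, psi)
    list(auc = mean(K), v10 = rowMeans(K), v01 = colMeans(K))
  }
  ca <- comp(sa)
  cb <- comp(sb)
  m <- length(ca$v10)
  n <- length(ca$v01)
  var_diff <- stats::var(ca$v10 - cb$v10) / m +
    stats::var(ca$v01 - cb$v01) / n
  dauc <- ca$auc - cb$auc
  z <- if (var_diff > 0) dauc / sqrt(var_diff) else 0
  list(auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff, z = z,
       p_value = if (var_diff > 0) 2 * stats::pnorm(-abs(z)) else 1)
}

# Brute-force windowed rolling min / rolling mean baseline (edge-truncated
# windows), mirroring the documented baseline definition.
oracle_baseline <- function(x, window) {
  h <- (window - 1) %/% 2
  n <- length(x)
  rmin <- vapply(seq_len(n), function(i)
    min(x[max(1, i - h):min(n, i + h)]), numeric(1))
  vapply(seq_len(n), function(i)
    mean(rmin[max(1, i - h):min(n, i + h)]), numeric(1))
}

# Exhaustive integer-lag cross-correlation scan.
oracle_best_lag <- function(x, r, max_shift) {
  lags <- seq(-max_shift, max_shift)
  n <- length(x)
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(x[seq_len(n - l) + l] * r[seq_len(n - l)])
    else sum(x[seq_len(n + l)] * r[seq_len(n + l) - l])
  }, numeric(1))
  ord <- order(abs(lags), lags)
  lags[ord][which.max(cc[ord])]
}

# PR area by direct enumeration over every distinct threshold.
oracle_pr_area <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  recall <- 0
  precision <- 1
  area <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    r2 <- tp / np
    p2 <- tp / sum(pred)
    area <- area + (r2 - recall) * (precision + p2) / 2
    recall <- r2
    precision <- p2
  }
  area
}

# mean silhouette width of a 2-group labelling in a coordinate embedding
mean_silhouette <- function(coords, groups) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- groups == groups[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(groups), groups[i]), function(g)
      mean(d[i, groups == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
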