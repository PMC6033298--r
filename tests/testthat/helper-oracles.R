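# Independent oracles used across the suite. Deliberately naive: each one
# recomputes the quantity by the most literal definition available.

# circular-window local mean / population sd with edge clamping
naive_local_stats <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  mu <- matrix(0, h, w); sdv <- matrix(0, h, w)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ys <- pmin(pmax(i + offs$dy, 1), h)
      xs <- pmin(pmax(j + offs$dx, 1), w)
      vals <- m[cbind(ys, xs)]
      mu[i, j] <- mean(vals)
      sdv[i, j] <- sqrt(mean((vals - mean(vals))^2))
    }
  }
  list(mean = mu, sd = sdv)
}

# AUC as the O(n^2) pairwise rank statistic, ties half-weighted
auc_pair_oracle <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# ROC by explicit threshold enumeration
roc_brute <- function(scores, truth) {
  ths <- sort(unique(scores), decreasing = TRUE)
  fpr <- c(0, vapply(ths, function(t) mean(scores[!truth] >= t), numeric(1)))
  tpr <- c(0, vapply(ths, function(t) mean(scores[truth] >= t), numeric(1)))
  data.frame(fpr = fpr, tpr = tpr)
}

# a circle-pair mask: two radius-r disks with centers d apart
circle_pair_mask <- function(h, w, r, d, c1 = NULL) {
  if (is.null(c1)) c1 <- c(h / 2, (w - d) / 2)
  c2 <- c1 + c(0, d)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((yy - c1[1])^2 + (xx - c1[2])^2 <= r^2) |
    ((yy - c2[1])^2 + (xx - c2[2])^2 <= r^2)
}

# best-of-permutations agreement between two 2-class labelings
label_agreement <- function(a, b) {
  max(mean(a == b), mean(a != b))
}
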