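# Independent brute-force oracles. Each is written from first principles,
# not by calling the package's statistical helpers.

# midranks computed from scratch (ties get the average position)
oracleMidranks <- function(v) {
  n <- length(v)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  r
}

# explicit average-rank Spearman coefficient via the covariance formula
oracleSpearman <- function(x, y) {
  rx <- oracleMidranks(x); ry <- oracleMidranks(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# exact two-sided permutation p-value over all n! orderings of y
oraclePermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in oraclePermutations(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

oracleSpearmanPermP <- function(x, y) {
  rx <- oracleMidranks(x); ry <- oracleMidranks(y)
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  den <- sqrt(sum(cx^2) * sum(cy^2))
  obs <- abs(sum(cx * cy) / den)
  vals <- vapply(oraclePermutations(length(y)),
                 function(p) abs(sum(cx * cy[p]) / den), 0)
  mean(vals >= obs - 1e-12)
}

# literal Benjamini-Hochberg step-up
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(1, p[o[i]] * m / i)
    prev <- min(prev, val)
    q[o[i]] <- prev
  }
  q
}

# upper-tail hypergeometric by explicit combinatorial sum
oracleHyperUpper <- function(overlap, nSuccess, nPop, nDraw) {
  ks <- overlap:min(nSuccess, nDraw)
  ks <- ks[ks >= max(0, nDraw - (nPop - nSuccess))]
  if (length(ks) == 0L) return(0)
  sum(choose(nSuccess, ks) * choose(nPop - nSuccess, nDraw - ks)) /
    choose(nPop, nDraw)
}

# exact rank-sum p by bitmask enumeration of group assignments
oracleRankSumP <- function(x1, x2, alternative = "greater") {
  n1 <- length(x1); n <- n1 + length(x2)
  r <- oracleMidranks(c(x1, x2))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) != n1) next
    total <- total + 1L
    Wb <- sum(r[bits == 1L])
    ok <- if (alternative == "greater") Wb >= W - 1e-9
          else abs(Wb - mu) >= abs(W - mu) - 1e-9
    if (ok) hits <- hits + 1L
  }
  hits / total
}

# AUC by concordant-pair counting (ties count one half)
oracleAUC <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# two-group log-rank chi-square by explicit risk-set summation
oracleLogrank <- function(time, event, group1) {
  ts <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0
  for (t in ts) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & group1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group1)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) return(0)
  OmE^2 / V
}

# OLS coefficients via the normal equations
oracleOLS <- function(X, y) {
  Xi <- cbind(1, X)
  as.numeric(solve(t(Xi) %*% Xi, t(Xi) %*% y))
}
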