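# Shared statistical primitives. Spearman uses average ranks and the
# t-approximation for the two-sided p-value; constant vectors are reported
# as (rho = 0, p = 1, flagged) so table shapes stay stable.

#' Spearman correlation with permutation-exact or t-approximation p-value
#'
#' Average-rank Spearman coefficient. For n <= 8 samples the two-sided
#' p-value is exact, from the full permutation distribution of the rank
#' correlation (valid under ties); for larger n it uses the t
#' approximation on n - 2 degrees of freedom. If either vector is constant
#' the correlation is undefined; the convention (rho = 0, p = 1,
#' `flagged = TRUE`) is returned.
#'
#' @param x,y numeric vectors of equal length (n >= 4 recommended).
#' @return list with `rho`, `p`, `n`, `flagged`.
#' @export
spearmanRho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L || sd(x) == 0 || sd(y) == 0)
    return(list(rho = 0, p = 1, n = n, flagged = TRUE))
  rho <- cor(rank(x), rank(y))
  # numerical guard: rank-correlations can exceed 1 by epsilon
  rho <- max(-1, min(1, rho))
  p <- if (n <= 8L) exactSpearmanP(x, y, rho) else spearmanPFromRho(rho, n)
  list(rho = rho, p = p, n = n, flagged = FALSE)
}

# all permutations of seq_len(n) as an (n! x n) matrix
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# exact two-sided permutation p-value of the rank correlation:
# P(|rho_perm| >= |rho_obs|) over all n! orderings of y
exactSpearmanP <- function(x, y, rhoObs) {
  rx <- rank(x); ry <- rank(y)
  n <- length(rx)
  P <- allPermutations(n)
  zx <- (rx - mean(rx)) / sqrt(sum((rx - mean(rx))^2))
  yc <- ry - mean(ry)
  nrm <- sqrt(sum(yc^2))
  rhoPerm <- (matrix(yc[P], nrow(P), n) %*% zx) / nrm
  mean(abs(rhoPerm) >= abs(rhoObs) - 1e-12)
}

spearmanPFromRho <- function(rho, n) {
  if (n < 3L) return(1)
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
}

# |rho| threshold equivalent to two-sided t-approximation p < alpha at n
spearmanRhoCritical <- function(alpha, n) {
  tc <- qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

# Row-wise standardized ranks: each row is replaced by its average ranks,
# centered and scaled to unit Euclidean norm, so the Spearman rho of two
# rows is their dot product. Constant rows come back as all-zero and are
# marked in the "constant" attribute.
standardizedRankRows <- function(M) {
  R <- t(apply(M, 1L, rank))
  if (ncol(M) == 1L) R <- matrix(R, nrow = nrow(M))  # apply() edge case
  R <- R - rowMeans(R)
  nrm <- sqrt(rowSums(R^2))
  const <- nrm == 0
  nrm[const] <- 1
  Z <- R / nrm
  attr(Z, "constant") <- const
  Z
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjusted p-values (monotone, capped at 1). A thin validated
#' wrapper around [stats::p.adjust()]; `NA` input is an error because every
#' downstream significance call depends on a complete q column.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
bhFDR <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p)) stop("bhFDR: NA p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("bhFDR: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Upper-tail hypergeometric p: probability of drawing >= `overlap` successes
# in `nDraw` draws from a population of `nPop` with `nSuccess` successes.
hypergeomUpperP <- function(overlap, nSuccess, nPop, nDraw) {
  phyper(overlap - 1, nSuccess, nPop - nSuccess, nDraw, lower.tail = FALSE)
}

# Rank-based AUC of `scores` for the positive class in `labels` (logical or
# +1/-1); midranks give the usual tie handling.
aucScore <- function(scores, positive) {
  positive <- as.logical(positive > 0 | positive == TRUE)
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Wilcoxon rank-sum p-value, exact for small groups
#'
#' Midrank Wilcoxon rank-sum test of `x1` against `x2`. When both groups
#' have at most 8 observations the p-value is exact, by enumeration of all
#' group assignments of the pooled midranks (tail convention:
#' one-sided `P(W >= W_obs)`, two-sided `P(|W - mu| >= |W_obs - mu|)`);
#' larger groups use the tie-corrected normal approximation without
#' continuity correction.
#'
#' @param x1,x2 numeric vectors; the alternative is that `x1` tends larger.
#' @param alternative `"greater"` or `"two.sided"`.
#' @return list with `p` and `statistic` (rank-sum W of `x1`).
#' @export
rankSumP <- function(x1, x2, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n1 <- length(x1); n2 <- length(x2); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty")
  r <- rank(c(x1, x2))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (max(n1, n2) <= 8L) {
    sets <- combn(n, n1)
    Wnull <- colSums(matrix(r[sets], nrow(sets), ncol(sets)))
    p <- if (alternative == "greater") mean(Wnull >= W - 1e-9)
         else mean(abs(Wnull - mu) >= abs(W - mu) - 1e-9)
  } else {
    z <- rankSumZ(x1, x2)
    p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
         else 2 * pnorm(abs(z), lower.tail = FALSE)
  }
  list(p = p, statistic = W)
}

# Normal-approximation rank-sum z statistic (midranks, tie-corrected) of
# group1 vs group2; positive when group1 tends larger.
rankSumZ <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2); n <- n1 + n2
  r <- rank(c(x1, x2))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(0)
  (W - mu) / sqrt(sig2)
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
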