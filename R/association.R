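# Raw-data association layer: per-condition Spearman tables, BH control,
# the gene-label permutation null for coupling enrichment, and the
# cohort-level contrasts (expressed-gene enrichment, substrate/product
# shift, differential-expression vs coupling, variance shift).

#' Spearman association table for connected gene-metabolite pairs
#'
#' Computes the average-rank Spearman correlation between each pair's gene
#' expression and metabolite level across the samples of one stratum, with
#' two-sided p-values from the t-approximation and Benjamini-Hochberg
#' q-values within the stratum. Pairs whose gene or metabolite vector is
#' constant are emitted with (rho = 0, p = 1, `flagged`).
#'
#' @param cohort a [GMCohort-class]; pairs must reference measured entities.
#' @param pairs data.frame from [connectedGMPairs()] (columns `gene_id`,
#'   `metabolite_id`; extra columns ignored).
#' @param stratum `"all"`, `"noncancerous"` or `"cancer"`.
#' @return data.frame with columns `gene_id`, `metabolite_id`, `stratum`,
#'   `rho`, `p`, `q`, `n_samples`, `flagged`.
#' @export
spearmanTable <- function(cohort, pairs,
                          stratum = c("all", "noncancerous", "cancer")) {
  stratum <- match.arg(stratum)
  idx <- stratumSamples(cohort, stratum)
  if (length(idx) < 4L) stop("stratum has fewer than 4 samples")
  expr <- expressionMatrix(cohort)[, idx, drop = FALSE]
  metab <- metaboliteMatrix(cohort)[, idx, drop = FALSE]
  missG <- setdiff(unique(pairs$gene_id), rownames(expr))
  missM <- setdiff(unique(pairs$metabolite_id), rownames(metab))
  if (length(missG) || length(missM))
    stop("pairs reference unmeasured entities: ",
         paste(c(missG, missM), collapse = ", "))

  gUse <- unique(pairs$gene_id); mUse <- unique(pairs$metabolite_id)
  Zg <- standardizedRankRows(expr[gUse, , drop = FALSE])
  Zm <- standardizedRankRows(metab[mUse, , drop = FALSE])
  gi <- match(pairs$gene_id, gUse); mi <- match(pairs$metabolite_id, mUse)
  rho <- rowSums(Zg[gi, , drop = FALSE] * Zm[mi, , drop = FALSE])
  rho <- pmax(-1, pmin(1, rho))
  flagged <- attr(Zg, "constant")[gi] | attr(Zm, "constant")[mi]
  rho[flagged] <- 0
  n <- length(idx)
  p <- if (n <= 8L) vapply(seq_len(nrow(pairs)), function(i)
         exactSpearmanP(expr[pairs$gene_id[i], ],
                        metab[pairs$metabolite_id[i], ], rho[i]), 0)
       else vapply(rho, spearmanPFromRho, 0, n = n)
  p[flagged] <- 1
  data.frame(gene_id = pairs$gene_id, metabolite_id = pairs$metabolite_id,
             stratum = stratum, rho = rho, p = p, q = bhFDR(p),
             n_samples = n, flagged = flagged, stringsAsFactors = FALSE)
}

#' Gene-label permutation test for coupling enrichment
#'
#' Measures whether connected gene-metabolite pairs are more often
#' significantly correlated than random pairs. The observed statistic is the
#' number of connected pairs with unadjusted Spearman p < `alpha`. Each of
#' `nPerm` permutations permutes the gene labels and draws `C = nrow(pairs)`
#' random gene-metabolite pairs (without replacement from the measured
#' grid), counting significant associations among them. The empirical
#' p-value is `(r + 1) / (nPerm + 1)` where `r` is the number of
#' permutations whose null count strictly exceeds the observed count.
#'
#' @inheritParams spearmanTable
#' @param alpha per-pair significance level (unadjusted), default 0.05.
#' @param nPerm number of permutations, default 1000.
#' @param seed integer RNG seed.
#' @return object of class `couplingPermTest`: list with `n_sig_real`,
#'   `n_sig_perm` (length `nPerm`), `r`, `n_perm`, `empiric_p`, `alpha`,
#'   `stratum`.
#' @export
couplingPermutationTest <- function(cohort, pairs,
                                    stratum = c("all", "noncancerous",
                                                "cancer"),
                                    alpha = 0.05, nPerm = 1000, seed = 1) {
  stratum <- match.arg(stratum)
  C <- nrow(pairs)
  if (C < 1L) stop("need at least one connected pair")
  if (nPerm < 1L) stop("nPerm must be >= 1")
  idx <- stratumSamples(cohort, stratum)
  expr <- expressionMatrix(cohort)[, idx, drop = FALSE]
  metab <- metaboliteMatrix(cohort)[, idx, drop = FALSE]
  nG <- nrow(expr); nM <- nrow(metab)
  if (C > nG * nM) stop("more pairs than possible random gene-metabolite pairs")
  n <- length(idx)

  Zg <- standardizedRankRows(expr)
  Zm <- standardizedRankRows(metab)
  rhoCrit <- spearmanRhoCritical(alpha, n)
  countSig <- function(gi, mi) {
    rho <- rowSums(Zg[gi, , drop = FALSE] * Zm[mi, , drop = FALSE])
    ok <- !(attr(Zg, "constant")[gi] | attr(Zm, "constant")[mi])
    sum(ok & abs(rho) > rhoCrit)
  }
  realCount <- countSig(match(pairs$gene_id, rownames(expr)),
                        match(pairs$metabolite_id, rownames(metab)))
  nullCounts <- withSeed(seed, vapply(seq_len(nPerm), function(b) {
    perm <- sample.int(nG)            # permuted gene labels
    cell <- sample.int(nG * nM, C)    # C random GM pairs, no replacement
    gi <- perm[((cell - 1L) %% nG) + 1L]
    mi <- ((cell - 1L) %/% nG) + 1L
    countSig(gi, mi)
  }, 0L))
  r <- sum(nullCounts > realCount)
  structure(list(n_sig_real = realCount, n_sig_perm = nullCounts, r = r,
                 n_perm = nPerm, empiric_p = (r + 1) / (nPerm + 1),
                 alpha = alpha, stratum = stratum),
            class = "couplingPermTest")
}

#' @export
print.couplingPermTest <- function(x, ...) {
  cat(sprintf(
    "Coupling permutation test [%s]: %d significant real pairs; empiric p = %.4g (r = %d / %d)\n",
    x$stratum, x$n_sig_real, x$empiric_p, x$r, x$n_perm))
  invisible(x)
}

#' Enrichment of highly expressed genes among significantly coupled genes
#'
#' Upper-tail hypergeometric test of the overlap between genes carrying at
#' least one FDR-significant association and highly expressed genes (mean
#' expression above the given quantile across the stratum), within the
#' population of all genes participating in measured pairs.
#'
#' @param cohort a [GMCohort-class].
#' @param assocTable output of [spearmanTable()] for one stratum.
#' @param alpha FDR level applied to the `q` column, default 0.05.
#' @param expressionQuantile cutoff defining "highly expressed" (default
#'   0.75, i.e. top quartile of mean expression).
#' @return list with `p`, `overlap`, `nSignif`, `nHigh`, `nPopulation`.
#' @export
expressedGeneEnrichment <- function(cohort, assocTable, alpha = 0.05,
                                    expressionQuantile = 0.75) {
  stopifnot(length(unique(assocTable$stratum)) == 1L)
  idx <- stratumSamples(cohort, unique(assocTable$stratum))
  pop <- unique(assocTable$gene_id)
  sig <- unique(assocTable$gene_id[assocTable$q < alpha])
  mexp <- rowMeans(expressionMatrix(cohort)[pop, idx, drop = FALSE])
  high <- pop[mexp > quantile(mexp, expressionQuantile)]
  if (length(high) == 0L) stop("empty highly-expressed draw set")
  ov <- length(intersect(sig, high))
  list(p = hypergeomUpperP(ov, length(sig), length(pop), length(high)),
       overlap = ov, nSignif = length(sig), nHigh = length(high),
       nPopulation = length(pop))
}

#' One-sided shift test: products vs substrates
#'
#' One-sided Wilcoxon rank-sum test ([rankSumP()]; exact for groups of at
#' most 8) that product-role values (correlations or classifier
#' confidences) are stochastically greater than substrate-role values.
#'
#' @param values numeric vector of per-triplet (or per-pair) values.
#' @param isSubstrate logical vector, `TRUE` for substrate-role entries.
#' @return list with `p` and `statistic` (the rank-sum W of the product
#'   group).
#' @export
substrateProductShift <- function(values, isSubstrate) {
  prod <- values[!isSubstrate]; sub <- values[isSubstrate]
  if (length(prod) == 0L || length(sub) == 0L)
    stop("both role groups must be nonempty")
  rankSumP(prod, sub, "greater")
}

#' Differential expression magnitude vs coupling strength
#'
#' Per gene: differential-expression magnitude between conditions as the
#' absolute tie-corrected rank-sum z-statistic, and coupling strength as the
#' maximum absolute Spearman rho over the gene's measured pairs
#' (all-samples stratum). Returns the Spearman correlation between the two
#' gene-level vectors.
#'
#' @param cohort a [GMCohort-class] with both conditions present.
#' @param assocTable output of [spearmanTable()] (stratum `"all"`).
#' @return list with `rho`, `p`, `n` (genes), `flagged`, and the per-gene
#'   data.frame `perGene` (`gene_id`, `diffexp`, `coupling`).
#' @export
diffexpVsCoupling <- function(cohort, assocTable) {
  cond <- conditionLabels(cohort)
  if (length(unique(cond)) < 2L) stop("both conditions must be present")
  genes <- unique(assocTable$gene_id)
  expr <- expressionMatrix(cohort)
  de <- vapply(genes, function(g)
    abs(rankSumZ(expr[g, cond == "cancer"],
                 expr[g, cond == "noncancerous"])), 0)
  coup <- vapply(genes, function(g)
    max(abs(assocTable$rho[assocTable$gene_id == g])), 0)
  res <- spearmanRho(de, coup)
  res$perGene <- data.frame(gene_id = genes, diffexp = de, coupling = coup,
                            stringsAsFactors = FALSE)
  res
}

#' Expression-variance shift of coupling-associated genes
#'
#' One-sided Wilcoxon rank-sum test that the expression variances of
#' RGM-associated genes exceed those of the remaining genes.
#'
#' @param expression genes x samples matrix (or a [GMCohort-class]).
#' @param associatedGenes character vector of associated gene IDs.
#' @return list with `p` and `statistic`.
#' @export
rgmGeneVarianceShift <- function(expression, associatedGenes) {
  if (is(expression, "GMCohort")) expression <- expressionMatrix(expression)
  v <- apply(expression, 1L, var)
  inSet <- rownames(expression) %in% associatedGenes
  if (!any(inSet) || all(inSet)) stop("both gene groups must be nonempty")
  rankSumP(v[inSet], v[!inSet], "greater")
}
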