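# Clinical application: Kaplan-Meier median-split survival screening of
# (predicted) metabolite levels, gene-vs-metabolite survival comparison,
# and ER-status differential analysis.

#' Median-split log-rank test for one metabolite
#'
#' Samples with value less than or equal to the median form the 'low'
#' group; the standard two-group log-rank statistic (chi-square, 1 df)
#' tests survival-curve separation. The direction reports which group has
#' better survival (fewer observed than expected events).
#'
#' @param values numeric vector, one (predicted) metabolite level per
#'   sample.
#' @param time survival times (months).
#' @param event logical/0-1 event indicator.
#' @return one-row data.frame with `statistic`, `p`, `direction`
#'   (`"low_better"` / `"high_better"` / `"none"`), `n_low`, `n_high`,
#'   `flagged` (`TRUE` when ties empty a group or groups are too small).
#' @export
kmLogrankMedianSplit <- function(values, time, event) {
  stopifnot(length(values) == length(time), length(time) == length(event))
  grp <- factor(ifelse(values <= median(values), "low", "high"),
                levels = c("low", "high"))
  nLow <- sum(grp == "low"); nHigh <- sum(grp == "high")
  if (nLow < 2L || nHigh < 2L)
    return(data.frame(statistic = NA_real_, p = NA_real_,
                      direction = "none", n_low = nLow, n_high = nHigh,
                      flagged = TRUE, stringsAsFactors = FALSE))
  sd_ <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ grp)
  p <- pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  direction <- if (sd_$chisq == 0) "none"
  else if (sd_$obs[1L] < sd_$exp[1L]) "low_better" else "high_better"
  data.frame(statistic = unname(sd_$chisq), p = p, direction = direction,
             n_low = nLow, n_high = nHigh, flagged = FALSE,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier curve data for a median split
#'
#' @inheritParams kmLogrankMedianSplit
#' @return data.frame with `time`, `survival`, `group` suitable for
#'   plotting step curves.
#' @export
kmCurveData <- function(values, time, event) {
  grp <- factor(ifelse(values <= median(values), "low", "high"),
                levels = c("low", "high"))
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ grp)
  strata <- rep(names(fit$strata), fit$strata)
  data.frame(time = fit$time, survival = fit$surv,
             group = sub("^grp=", "", strata), stringsAsFactors = FALSE)
}

#' Survival screen over a metabolite matrix
#'
#' Runs [kmLogrankMedianSplit()] for every metabolite row against the
#' cohort's survival data, with BH adjustment across metabolites.
#'
#' @param metabMatrix metabolites x samples matrix (typically
#'   [predictMetabolites()] output).
#' @param clinical data.frame with rownames = samples and columns
#'   `survival_time`, `event` (e.g. [sampleData()]).
#' @param alpha FDR level for the `significant` flag, default 0.05.
#' @return data.frame, one row per metabolite: `metabolite_id`,
#'   `statistic`, `p`, `q`, `direction`, `n_low`, `n_high`, `flagged`,
#'   `significant`.
#' @export
survivalScreen <- function(metabMatrix, clinical, alpha = 0.05) {
  samples <- intersect(colnames(metabMatrix), rownames(clinical))
  cl <- clinical[samples, , drop = FALSE]
  ok <- is.finite(cl$survival_time) & !is.na(cl$event)
  samples <- samples[ok]; cl <- cl[ok, , drop = FALSE]
  rows <- lapply(rownames(metabMatrix), function(m) {
    r <- kmLogrankMedianSplit(metabMatrix[m, samples], cl$survival_time,
                              cl$event)
    cbind(data.frame(metabolite_id = m, stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  pAdj <- out$p
  pAdj[is.na(pAdj)] <- 1  # flagged rows carry no evidence
  out$q <- bhFDR(pAdj)
  out$significant <- !is.na(out$p) & out$q < alpha
  out[order(out$p), , drop = FALSE]
}

#' Compare metabolite-level vs gene-level survival signal
#'
#' For each screened metabolite, the same median-split log-rank test is run
#' on the expression of every gene connected to it in the network; the
#' metabolite is flagged `stronger` when its log-rank p is smaller than the
#' aggregated gene p (`rule = "min"`: the most favorable single gene;
#' `rule = "mean"`: the mean gene p).
#'
#' @param screen output of [survivalScreen()].
#' @param expression genes x samples expression matrix of the same cohort.
#' @param network the [MetabolicNetwork-class].
#' @param clinical clinical data.frame as in [survivalScreen()].
#' @param rule `"min"` (default) or `"mean"`.
#' @return `screen` with columns `best_gene_p`, `n_genes_tested`,
#'   `stronger` (`NA` when no connected gene is measured).
#' @export
geneVsMetaboliteSurvival <- function(screen, expression, network, clinical,
                                     rule = c("min", "mean")) {
  rule <- match.arg(rule)
  pairs <- connectedGMPairs(network)
  samples <- intersect(colnames(expression), rownames(clinical))
  cl <- clinical[samples, , drop = FALSE]
  ok <- is.finite(cl$survival_time) & !is.na(cl$event)
  samples <- samples[ok]; cl <- cl[ok, , drop = FALSE]
  genePCache <- new.env(parent = emptyenv())
  geneP <- function(g) {
    if (!is.null(genePCache[[g]])) return(genePCache[[g]])
    p <- kmLogrankMedianSplit(expression[g, samples], cl$survival_time,
                              cl$event)$p
    genePCache[[g]] <- p
    p
  }
  res <- lapply(seq_len(nrow(screen)), function(i) {
    m <- screen$metabolite_id[i]
    gs <- pairs$gene_id[pairs$metabolite_id == m]
    gs <- gs[gs %in% rownames(expression)]
    if (length(gs) == 0L)
      return(data.frame(best_gene_p = NA_real_, n_genes_tested = 0L,
                        stronger = NA))
    ps <- vapply(gs, geneP, 0)
    agg <- if (rule == "min") min(ps, na.rm = TRUE)
           else mean(ps, na.rm = TRUE)
    data.frame(best_gene_p = agg, n_genes_tested = length(gs),
               stronger = !is.na(screen$p[i]) && screen$p[i] < agg)
  })
  cbind(screen, do.call(rbind, res))
}

#' ER-status differential metabolites
#'
#' Two-sided Wilcoxon rank-sum test per metabolite between ER-positive and
#' ER-negative samples, BH-adjusted across metabolites; the fold direction
#' is the median ER+/ER- ratio on the level scale.
#'
#' @param metabMatrix metabolites x samples matrix.
#' @param erStatus 0/1 vector (1 = ER positive) named by or aligned with
#'   the matrix columns.
#' @param alpha FDR level, default 0.05.
#' @return data.frame with `metabolite_id`, `p`, `q`, `median_diff`
#'   (ER+ minus ER- median), `significant`, ordered by `p`.
#' @export
erDifferential <- function(metabMatrix, erStatus, alpha = 0.05) {
  er <- as.integer(erStatus)
  if (length(unique(er[!is.na(er)])) < 2L)
    stop("both ER groups must be nonempty")
  rows <- lapply(rownames(metabMatrix), function(m) {
    v <- metabMatrix[m, ]
    wt <- rankSumP(v[er == 1L], v[er == 0L], "two.sided")
    p <- wt$p
    if (!is.finite(p)) p <- 1
    data.frame(metabolite_id = m, p = p,
               median_diff = median(v[er == 1L]) - median(v[er == 0L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhFDR(out$p)
  out$significant <- out$q < alpha
  out[order(out$p), , drop = FALSE]
}

#' Fold change between conditions on the abundance scale
#'
#' Median cancer over median noncancerous level per metabolite.
#'
#' @param metabMatrix metabolites x samples abundance matrix.
#' @param condition per-sample condition labels.
#' @return named numeric vector of fold changes.
#' @export
conditionFoldChange <- function(metabMatrix, condition) {
  apply(metabMatrix, 1L, function(v)
    median(v[condition == "cancer"]) / median(v[condition == "noncancerous"]))
}
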