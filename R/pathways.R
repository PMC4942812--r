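# Pathway-level analyses: prediction-based regulated-reaction enrichment,
# the raw-data GM association shift test, and cross-dataset agreement.

#' Reactions regulated in a condition
#'
#' A reaction is regulated when at least one of its RGM triplets carries an
#' FDR-significant confidence level in that condition.
#'
#' @param sigTable output of [confidenceSignificance()] aligned with
#'   `triplets`.
#' @param triplets the triplet data.frame the confidences were computed for.
#' @return character vector of regulated reaction IDs.
#' @export
regulatedReactions <- function(sigTable, triplets) {
  stopifnot(nrow(sigTable) == nrow(triplets))
  sort(unique(triplets$reaction_id[sigTable$significant]))
}

#' Prediction-based pathway enrichment of regulated reactions
#'
#' Per condition and pathway, an upper-tail hypergeometric test: population
#' = all reactions with enumerable triplets, successes = reactions
#' regulated in the condition, draws = the pathway's reactions; BH-adjusted
#' across pathways within each condition.
#'
#' @param regulatedByCondition named list of regulated reaction ID vectors,
#'   e.g. `list(cancer = ..., noncancerous = ...)`.
#' @param network the [MetabolicNetwork-class].
#' @param triplets triplet universe defining the reaction population.
#' @return data.frame with `condition`, `pathway`, `pathway_id`,
#'   `n_regulated`, `n_total`, `p`, `q`.
#' @export
predictionEnrichment <- function(regulatedByCondition, network, triplets) {
  rx <- reactions(network)
  popRx <- sort(unique(triplets$reaction_id))
  rxPath <- rx[match(popRx, rx$reaction_id), c("pathway", "pathway_id")]
  paths <- unique(rxPath)
  out <- lapply(names(regulatedByCondition), function(cond) {
    reg <- intersect(regulatedByCondition[[cond]], popRx)
    rows <- lapply(seq_len(nrow(paths)), function(i) {
      inPath <- popRx[rxPath$pathway_id == paths$pathway_id[i]]
      if (length(inPath) == 0L) return(NULL)  # empty pathway: skipped
      ov <- length(intersect(reg, inPath))
      data.frame(condition = cond, pathway = paths$pathway[i],
                 pathway_id = paths$pathway_id[i],
                 n_regulated = ov, n_total = length(inPath),
                 p = hypergeomUpperP(ov, length(reg), length(popRx),
                                     length(inPath)),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$q <- bhFDR(tab$p)
    tab
  })
  do.call(rbind, out)
}

#' Raw-data pathway shift in GM association strength
#'
#' For each pathway with at least `minPairs` measured connected pairs, a
#' two-sided Wilcoxon rank-sum test comparing the pathway's per-pair
#' Spearman p-values between the noncancerous and cancer strata (the
#' direction is reported as the median noncancerous-minus-cancer p-value
#' difference); BH-adjusted across eligible pathways.
#'
#' @param assocNoncancerous,assocCancer [spearmanTable()] outputs for the
#'   two strata over the same measured pairs.
#' @param network the [MetabolicNetwork-class] (pair-pathway membership via
#'   connecting reactions).
#' @param pairs the connected pairs the tables were computed on (with
#'   `reaction_ids`).
#' @param minPairs minimum measured pairs per pathway, default 10.
#' @return data.frame with `pathway`, `pathway_id`, `n_pairs`, `p`, `q`,
#'   `median_diff`; zero rows (with a message) when no pathway is eligible.
#' @export
rawGMShift <- function(assocNoncancerous, assocCancer, network, pairs,
                       minPairs = 10) {
  rx <- reactions(network)
  key <- function(tab) paste(tab$gene_id, tab$metabolite_id)
  pairKey <- paste(pairs$gene_id, pairs$metabolite_id)
  pNC <- assocNoncancerous$p[match(pairKey, key(assocNoncancerous))]
  pC <- assocCancer$p[match(pairKey, key(assocCancer))]
  if (anyNA(pNC) || anyNA(pC))
    stop("both strata tables must cover every connected pair")
  pairPaths <- lapply(pairs$reaction_ids, function(rxs)
    unique(rx$pathway_id[match(rxs, rx$reaction_id)]))
  allPaths <- sort(unique(unlist(pairPaths)))
  rows <- lapply(allPaths, function(pid) {
    ix <- which(vapply(pairPaths, function(v) pid %in% v, TRUE))
    if (length(ix) < minPairs) return(NULL)
    wt <- rankSumP(pNC[ix], pC[ix], "two.sided")
    data.frame(pathway = rx$pathway[match(pid, rx$pathway_id)],
               pathway_id = pid, n_pairs = length(ix),
               p = wt$p,
               median_diff = median(pNC[ix]) - median(pC[ix]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    message("no pathway reaches ", minPairs, " measured GM pairs")
    return(data.frame(pathway = character(0), pathway_id = integer(0),
                      n_pairs = integer(0), p = numeric(0), q = numeric(0),
                      median_diff = numeric(0)))
  }
  out <- do.call(rbind, rows)
  # degenerate all-tied comparisons return NaN from the normal
  # approximation; identical distributions carry no shift evidence
  out$p[!is.finite(out$p)] <- 1
  out$q <- bhFDR(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Cross-dataset agreement of pathway enrichment
#'
#' Spearman correlation of -log10 enrichment p-values over the pathways
#' significantly enriched (p < `sigLevel`) in either dataset, restricted to
#' shared pathway keys.
#'
#' @param tableA,tableB enrichment tables with `pathway_id` and `p`
#'   columns (one condition each).
#' @param sigLevel inclusion cutoff on the unadjusted enrichment p,
#'   default 0.05.
#' @return list with `rho`, `p`, `n` (shared significant pathways),
#'   `flagged` (`TRUE` when fewer than 4 shared pathways).
#' @export
crossDatasetAgreement <- function(tableA, tableB, sigLevel = 0.05) {
  shared <- intersect(tableA$pathway_id, tableB$pathway_id)
  pA <- tableA$p[match(shared, tableA$pathway_id)]
  pB <- tableB$p[match(shared, tableB$pathway_id)]
  keep <- pA <= sigLevel | pB <= sigLevel
  if (sum(keep) < 4L)
    return(list(rho = NA_real_, p = NA_real_, n = sum(keep),
                flagged = TRUE))
  res <- spearmanRho(-log10(pA[keep]), -log10(pB[keep]))
  list(rho = res$rho, p = res$p, n = sum(keep), flagged = res$flagged)
}
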