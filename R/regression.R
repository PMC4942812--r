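# Step 2 of the pipeline: select the extreme-confidence RGM per metabolite
# (GR+ and GR-), assemble 28-feature instances with the per-sample
# expression substituted into the gene-mean slot, fit one pooled OLS model,
# and predict z-scored log metabolite levels per sample.

#' Select the most positively and negatively coupled RGM per metabolite
#'
#' For each metabolite, `GR+` is the (gene, reaction) of its
#' maximum-confidence triplet and `GR-` that of its minimum-confidence
#' triplet; ties break by ascending (reaction index, gene index). A
#' metabolite is kept only when the larger of the two confidence magnitudes
#' exceeds `threshold`.
#'
#' @param confTable data.frame with columns `reaction_id`, `gene_id`,
#'   `metabolite_id`, `confidence` (e.g. [predictConfidences()] output with
#'   `triplets` supplied).
#' @param network the [MetabolicNetwork-class] (tie-break indices).
#' @param threshold minimum of the maximum absolute selected confidence,
#'   default 0.5.
#' @return list with `selection` data.frame (`metabolite_id`,
#'   `gene_plus`, `reaction_plus`, `conf_plus`, `gene_minus`,
#'   `reaction_minus`, `conf_minus`) and `excluded` (metabolite IDs failing
#'   the threshold or lacking triplets).
#' @export
selectRGMExtremes <- function(confTable, network, threshold = 0.5) {
  rx <- reactions(network); gi <- networkGenes(network)
  rIdx <- rx$network_index[match(confTable$reaction_id, rx$reaction_id)]
  gIdx <- gi$network_index[match(confTable$gene_id, gi$gene_id)]
  mets <- unique(confTable$metabolite_id)
  rows <- lapply(mets, function(m) {
    ix <- which(confTable$metabolite_id == m)
    oPlus <- ix[order(-confTable$confidence[ix], rIdx[ix], gIdx[ix])][1L]
    oMinus <- ix[order(confTable$confidence[ix], rIdx[ix], gIdx[ix])][1L]
    data.frame(metabolite_id = m,
               gene_plus = confTable$gene_id[oPlus],
               reaction_plus = confTable$reaction_id[oPlus],
               conf_plus = confTable$confidence[oPlus],
               gene_minus = confTable$gene_id[oMinus],
               reaction_minus = confTable$reaction_id[oMinus],
               conf_minus = confTable$confidence[oMinus],
               stringsAsFactors = FALSE)
  })
  sel <- do.call(rbind, rows)
  keep <- pmax(abs(sel$conf_plus), abs(sel$conf_minus)) > threshold
  list(selection = sel[keep, , drop = FALSE],
       excluded = sel$metabolite_id[!keep])
}

# 14-feature row of one (reaction, gene, metabolite, role) with feature 6
# left as the dataset mean; per-sample substitution happens in
# buildInstances.
selectionFeatureRow <- function(network, cohort, reaction, gene, metabolite,
                                isSubstrate) {
  tri <- data.frame(reaction_id = reaction, gene_id = gene,
                    metabolite_id = metabolite, is_substrate = isSubstrate,
                    stringsAsFactors = FALSE)
  buildFeatures(network, cohort, tri)$features[1L, ]
}

#' Assemble 28-feature regression instances
#'
#' One instance per (selected metabolite, sample): the `GR+` triplet's
#' 14-feature block followed by the `GR-` block, with the gene-mean slot
#' (feature 6) of each block replaced by that gene's expression in the
#' sample (`f6Mode = "per-sample"`, the default) so predictions vary across
#' samples. `f6Mode = "summary"` keeps the dataset-level mean in the slot
#' for fidelity experiments.
#'
#' @param selection the `selection` data.frame from [selectRGMExtremes()].
#' @param cohort the target [GMCohort-class] (expression source; features
#'   7-9 are computed over its samples).
#' @param network the [MetabolicNetwork-class].
#' @param f6Mode `"per-sample"` or `"summary"`.
#' @return list with `X` (instances x 28 matrix, columns `p1..p14`,
#'   `n1..n14`) and `meta` data.frame (`metabolite_id`, `sample_id`).
#'   Metabolites whose selected genes are unmeasured are dropped with a
#'   warning.
#' @export
buildInstances <- function(selection, cohort, network,
                           f6Mode = c("per-sample", "summary")) {
  f6Mode <- match.arg(f6Mode)
  expr <- expressionMatrix(cohort)
  samples <- colnames(expr)
  measurable <- selection$gene_plus %in% rownames(expr) &
    selection$gene_minus %in% rownames(expr)
  if (any(!measurable))
    warning("dropping metabolites with unmeasured selected genes: ",
            paste(selection$metabolite_id[!measurable], collapse = ", "))
  selection <- selection[measurable, , drop = FALSE]
  if (nrow(selection) == 0L) stop("no selectable metabolites remain")

  roleOf <- function(reaction, metabolite) {
    rm_ <- reactionMetaboliteLinks(network)
    roles <- rm_$role[rm_$reaction_id == reaction &
                      rm_$metabolite_id == metabolite]
    "substrate" %in% roles && !("product" %in% roles)
  }
  blocks <- lapply(seq_len(nrow(selection)), function(i) {
    s <- selection[i, ]
    bp <- selectionFeatureRow(network, cohort, s$reaction_plus, s$gene_plus,
                              s$metabolite_id,
                              roleOf(s$reaction_plus, s$metabolite_id))
    bm <- selectionFeatureRow(network, cohort, s$reaction_minus,
                              s$gene_minus, s$metabolite_id,
                              roleOf(s$reaction_minus, s$metabolite_id))
    base <- matrix(rep(c(bp, bm), each = length(samples)),
                   nrow = length(samples))
    if (f6Mode == "per-sample") {
      base[, 6L] <- expr[s$gene_plus, samples]
      base[, 20L] <- expr[s$gene_minus, samples]
    }
    base
  })
  X <- do.call(rbind, blocks)
  colnames(X) <- c(paste0("p", 1:14), paste0("n", 1:14))
  meta <- data.frame(
    metabolite_id = rep(selection$metabolite_id, each = length(samples)),
    sample_id = rep(samples, times = nrow(selection)),
    stringsAsFactors = FALSE)
  list(X = X, meta = meta)
}

#' Log-transform and z-score metabolite levels
#'
#' Natural log of positive abundances; when a metabolite has nonpositive
#' values, half its minimum positive value is added as a pseudo-offset
#' first. Each metabolite is then standardized with its own mean/SD, which
#' are returned so application cohorts can reuse frozen training statistics.
#'
#' @param metab metabolites x samples abundance matrix.
#' @return list with `z` (matrix), `center`, `scale` (per metabolite).
#' @export
logZScoreMetabolites <- function(metab) {
  L <- t(apply(metab, 1L, function(v) {
    if (any(v <= 0)) {
      off <- min(v[v > 0]) / 2
      if (!is.finite(off)) off <- 1
      v <- v + off
    }
    log(v)
  }))
  ctr <- rowMeans(L)
  scl <- apply(L, 1L, sd)
  scl[scl == 0] <- 1
  list(z = (L - ctr) / scl, center = ctr, scale = scl)
}

#' Fit the pooled metabolite-level regressor
#'
#' One ordinary-least-squares model (with intercept) over all
#' (metabolite, sample) instances; the "generalized" regressor shares its
#' coefficients across metabolites. A rank-deficient design falls back to
#' the Moore-Penrose pseudoinverse with a warning.
#'
#' @param X instance matrix from [buildInstances()].
#' @param y z-scored log metabolite targets aligned with `X` rows.
#' @return object of class `metRegressor` with `coef` (intercept first).
#' @export
fitMetaboliteRegressor <- function(X, y) {
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < ncol(X) + 1L)
    warning("fewer instances than coefficients; fit is underdetermined")
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    warning("rank-deficient design; using pseudoinverse")
    beta <- as.numeric(MASS::ginv(Xi) %*% y)
  } else {
    beta <- qr.coef(qrX, y)
  }
  names(beta) <- colnames(Xi)
  structure(list(coef = beta), class = "metRegressor")
}

#' @export
print.metRegressor <- function(x, ...) {
  cat(sprintf("Pooled metabolite regressor: %d coefficients (incl. intercept)\n",
              length(x$coef)))
  invisible(x)
}

#' Predict per-sample metabolite levels
#'
#' @param model a `metRegressor`.
#' @param instances output of [buildInstances()] (layout must match
#'   training).
#' @return metabolites x samples matrix of predicted z-scored log levels.
#' @export
predictMetabolites <- function(model, instances) {
  X <- instances$X
  if (ncol(X) + 1L != length(model$coef)) stop("instance layout mismatch")
  yhat <- as.numeric(cbind(1, X) %*% model$coef)
  meta <- instances$meta
  mets <- unique(meta$metabolite_id)
  samples <- unique(meta$sample_id)
  M <- matrix(NA_real_, length(mets), length(samples),
              dimnames = list(mets, samples))
  M[cbind(match(meta$metabolite_id, mets),
          match(meta$sample_id, samples))] <- yhat
  M
}

#' Evaluate predicted against measured metabolite levels
#'
#' Spearman correlations at three granularities: overall (pooling all
#' metabolite-sample points), per metabolite across samples, and per sample
#' across metabolites, with BH adjustment within each family. Measured
#' abundances are log-transformed and z-scored per metabolite
#' ([logZScoreMetabolites()]) before the pooled and per-sample statistics,
#' so those compare within-metabolite variation rather than between-
#' metabolite baseline levels; per-metabolite correlations are unaffected
#' (Spearman is invariant to within-row monotone transforms). Also reports
#' the meta-correlation between each metabolite's per-metabolite rho and
#' the magnitude of its strongest selected confidence, quantifying that
#' strongly coupled metabolites are predicted better.
#'
#' @param predicted metabolites x samples matrix from
#'   [predictMetabolites()].
#' @param measured metabolites x samples matrix of measured levels (any
#'   monotone scale; Spearman is transform-invariant).
#' @param selection optional `selection` from [selectRGMExtremes()] for the
#'   meta-correlation.
#' @return list with `overall` (rho, p, n), `perMetabolite` and `perSample`
#'   data.frames (`rho`, `p`, `q`, `flagged`), and `metaCorrelation` (rho,
#'   p) when `selection` is given.
#' @export
evaluatePredictions <- function(predicted, measured, selection = NULL) {
  mets <- intersect(rownames(predicted), rownames(measured))
  samples <- intersect(colnames(predicted), colnames(measured))
  if (length(mets) == 0L || length(samples) < 4L)
    stop("insufficient shared metabolites/samples")
  P <- predicted[mets, samples, drop = FALSE]
  M <- logZScoreMetabolites(measured[mets, samples, drop = FALSE])$z

  overall <- spearmanRho(as.numeric(P), as.numeric(M))
  fam <- function(ix, byRow) {
    rows <- lapply(ix, function(i) {
      pv <- if (byRow) P[i, ] else P[, i]
      mv <- if (byRow) M[i, ] else M[, i]
      r <- spearmanRho(pv, mv)
      data.frame(id = if (byRow) mets[i] else samples[i], rho = r$rho,
                 p = r$p, flagged = r$flagged || length(pv) < 4L,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- bhFDR(out$p)
    out
  }
  perMet <- fam(seq_along(mets), TRUE)
  names(perMet)[1L] <- "metabolite_id"
  perSam <- fam(seq_along(samples), FALSE)
  names(perSam)[1L] <- "sample_id"

  metaCor <- NULL
  if (!is.null(selection)) {
    strongest <- pmax(abs(selection$conf_plus), abs(selection$conf_minus))
    names(strongest) <- selection$metabolite_id
    shared <- intersect(perMet$metabolite_id, names(strongest))
    metaCor <- spearmanRho(perMet$rho[match(shared, perMet$metabolite_id)],
                           strongest[shared])
  }
  list(overall = overall, perMetabolite = perMet, perSample = perSam,
       metaCorrelation = metaCor)
}
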