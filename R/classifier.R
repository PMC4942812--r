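# Step 1 of the pipeline: the RGM predictor. A balanced linear-kernel SVM
# over 14 network + expression features per reaction-gene-metabolite
# triplet, labeled by the FDR-significant correlation sign of the triplet's
# gene-metabolite pair, emitting confidence levels in [-1, +1] genome-wide.

rgmFeatureNames <- paste0("f", 1:14)

#' Build the 14-feature representation of RGM triplets
#'
#' Features per triplet: (1) reaction network index; (2) pathway integer
#' code; (3) predicted delta G0; (4) reversibility flag; (5) gene network
#' index; (6-9) mean, variance, minimum and maximum of the gene's expression
#' across the stratum's samples; (10) metabolite network index; (11) total
#' distinct metabolites in the reaction; (12) substrate count; (13) product
#' count; (14) substrate/product flag (1 = substrate). Triplets whose gene
#' is not measured are excluded and listed.
#'
#' @param network a [MetabolicNetwork-class].
#' @param cohort a [GMCohort-class] (expression supplies features 6-9).
#' @param triplets data.frame from [enumerateRGMTriplets()].
#' @param stratum samples over which features 6-9 are computed.
#' @return list with `features` (matrix, columns `f1`..`f14`), `triplets`
#'   (kept rows, aligned with `features`), `excluded` (dropped rows).
#' @export
buildFeatures <- function(network, cohort, triplets,
                          stratum = c("all", "noncancerous", "cancer")) {
  stratum <- match.arg(stratum)
  idx <- stratumSamples(cohort, stratum)
  expr <- expressionMatrix(cohort)[, idx, drop = FALSE]
  measured <- triplets$gene_id %in% rownames(expr)
  excluded <- triplets[!measured, , drop = FALSE]
  triplets <- triplets[measured, , drop = FALSE]

  rx <- reactions(network)
  gi <- networkGenes(network); mi <- networkMetabolites(network)
  rm_ <- reactionMetaboliteLinks(network)
  nSub <- tapply(rm_$role == "substrate", rm_$reaction_id, sum)
  nProd <- tapply(rm_$role == "product", rm_$reaction_id, sum)
  nMet <- tapply(rm_$metabolite_id, rm_$reaction_id,
                 function(v) length(unique(v)))

  ri <- match(triplets$reaction_id, rx$reaction_id)
  g <- triplets$gene_id
  gm <- rowMeans(expr); gv <- apply(expr, 1L, var)
  gmin <- apply(expr, 1L, min); gmax <- apply(expr, 1L, max)

  F <- cbind(
    f1 = rx$network_index[ri],
    f2 = rx$pathway_id[ri],
    f3 = rx$delta_g0[ri],
    f4 = as.numeric(rx$reversible[ri]),
    f5 = gi$network_index[match(g, gi$gene_id)],
    f6 = gm[g], f7 = gv[g], f8 = gmin[g], f9 = gmax[g],
    f10 = mi$network_index[match(triplets$metabolite_id, mi$metabolite_id)],
    f11 = as.numeric(nMet[triplets$reaction_id]),
    f12 = as.numeric(nSub[triplets$reaction_id]),
    f13 = as.numeric(nProd[triplets$reaction_id]),
    f14 = as.numeric(triplets$is_substrate))
  F[is.na(F[, "f12"]), "f12"] <- 0
  F[is.na(F[, "f13"]), "f13"] <- 0
  rownames(F) <- NULL
  list(features = F, triplets = triplets, excluded = excluded)
}

#' Label RGM triplets from an association table
#'
#' A triplet inherits the label of its gene-metabolite pair: +1 when the
#' pair's FDR-adjusted p is below `alpha` with positive correlation, -1 when
#' significant with negative correlation, 0 (unlabeled) otherwise or when
#' the pair is unmeasured.
#'
#' @param assocTable output of [spearmanTable()] for the matching stratum.
#' @param triplets data.frame of triplets to label.
#' @param alpha FDR level, default 0.05.
#' @return integer vector (+1 / -1 / 0) aligned with `triplets`.
#' @export
buildLabels <- function(assocTable, triplets, alpha = 0.05) {
  key <- paste(assocTable$gene_id, assocTable$metabolite_id)
  lab <- ifelse(assocTable$q < alpha, sign(assocTable$rho), 0)
  out <- lab[match(paste(triplets$gene_id, triplets$metabolite_id), key)]
  out[is.na(out)] <- 0
  as.integer(out)
}

standardizeTrain <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  list(X = scale(X, center = ctr, scale = scl), center = ctr, scale = scl)
}

#' Train the balanced RGM classifier
#'
#' Subsamples the majority label class to the minority size (seeded), then
#' fits a linear-kernel maximum-margin classifier (C = 1 by default) on
#' z-scored features. The default `"margin"` confidence mapping reports the
#' decision value clipped to \[-1, +1\], which preserves the margin scale
#' that the label-permutation significance test compares against its null;
#' the `"calibrated"` alternative maps Platt probabilities as
#' `2 * P(+1 | x) - 1` (smoother, but recalibration makes real and
#' permuted classifiers share one scale, so it carries no significance
#' information).
#'
#' @param features feature matrix from [buildFeatures()].
#' @param labels integer labels (+1 / -1 / 0); only nonzero rows train.
#' @param seed integer RNG seed (balancing + calibration folds).
#' @param cost SVM regularization constant, default 1.
#' @param mapping `"margin"` (default) or `"calibrated"`.
#' @return object of class `rgmModel`.
#' @export
trainRGM <- function(features, labels, seed = 1, cost = 1,
                     mapping = c("margin", "calibrated")) {
  mapping <- match.arg(mapping)
  pos <- which(labels == 1L); neg <- which(labels == -1L)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both label classes must be nonempty")
  withSeed(seed, {
    k <- min(length(pos), length(neg))
    use <- c(sample(pos, k), sample(neg, k))
    std <- standardizeTrain(features[use, , drop = FALSE])
    y <- factor(labels[use], levels = c(-1L, 1L))
    fit <- e1071::svm(x = std$X, y = y, kernel = "linear", cost = cost,
                      scale = FALSE, probability = mapping == "calibrated")
    structure(list(svm = fit, center = std$center, scale = std$scale,
                   mapping = mapping, nPerClass = k, cost = cost,
                   trainRows = use),
              class = "rgmModel")
  })
}

#' @export
print.rgmModel <- function(x, ...) {
  cat(sprintf(
    "RGM classifier: linear kernel, C = %g, %d + %d balanced training triplets, %s confidence mapping\n",
    x$cost, x$nPerClass, x$nPerClass, x$mapping))
  invisible(x)
}

#' Predict confidence levels for RGM triplets
#'
#' Applies a trained [trainRGM()] model to a feature matrix and returns a
#' confidence level in \[-1, +1\] per triplet: values near +1 indicate a
#' confidently positive enzyme-metabolite association, near -1 a negative
#' one, and near 0 no interactional regulation.
#'
#' @param model an `rgmModel`.
#' @param features feature matrix (same 14 columns as training).
#' @param triplets optional triplet data.frame to bind the confidences to.
#' @return if `triplets` is given, that data.frame with a `confidence`
#'   column appended; otherwise the numeric confidence vector.
#' @export
predictConfidences <- function(model, features, triplets = NULL) {
  if (ncol(features) != length(model$center))
    stop("feature dimension mismatch")
  X <- scale(features, center = model$center, scale = model$scale)
  if (model$mapping == "calibrated") {
    pr <- predict(model$svm, X, probability = TRUE)
    conf <- 2 * attr(pr, "probabilities")[, "1"] - 1
  } else {
    dvm <- attr(predict(model$svm, X, decision.values = TRUE),
                "decision.values")
    dv <- dvm[, 1L]
    # decision column is "<levelA>/<levelB>"; orient so +1 means class "1"
    if (colnames(dvm)[1L] == "-1/1") dv <- -dv
    conf <- pmax(-1, pmin(1, dv))
  }
  conf <- unname(pmax(-1, pmin(1, conf)))
  if (is.null(triplets)) return(conf)
  triplets$confidence <- conf
  triplets
}

#' Stratified k-fold cross-validation of the RGM classifier
#'
#' Splits the labeled triplets into k folds stratified by label; each fold
#' is held out while the classifier is re-balanced, re-standardized and
#' re-trained on the remainder (no leakage), then scored on the held-out
#' confidences. AUC uses the rank formula; sensitivity, specificity and
#' accuracy threshold the confidence at 0.
#'
#' @inheritParams trainRGM
#' @param k number of folds, default 5.
#' @return object of class `rgmCV`: list with `perFold` data.frame,
#'   `meanAUC`, `meanSensitivity`, `meanSpecificity`, `meanAccuracy`,
#'   `folds` (data.frame of labeled rows with fold assignment, held-out
#'   `confidence` and `label`), `seed`.
#' @export
crossValidate <- function(features, labels, k = 5, seed = 1, cost = 1,
                          mapping = c("margin", "calibrated")) {
  mapping <- match.arg(mapping)
  labeled <- which(labels != 0L)
  if (length(labeled) < k) stop("fewer labeled triplets than folds")
  withSeed(seed, {
    foldOf <- integer(length(labeled))
    for (cls in c(1L, -1L)) {
      ix <- which(labels[labeled] == cls)
      foldOf[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
    foldSeeds <- sample.int(.Machine$integer.max %/% 2L, k)
    heldConf <- rep(NA_real_, length(labeled))
    perFold <- lapply(seq_len(k), function(f) {
      trIx <- labeled[foldOf != f]; teIx <- labeled[foldOf == f]
      m <- trainRGM(features[trIx, , drop = FALSE], labels[trIx],
                    seed = foldSeeds[f], cost = cost, mapping = mapping)
      conf <- predictConfidences(m, features[teIx, , drop = FALSE])
      heldConf[foldOf == f] <<- conf
      truth <- labels[teIx]
      pred <- ifelse(conf > 0, 1L, -1L)
      data.frame(
        fold = f,
        auc = aucScore(conf, truth == 1L),
        sensitivity = if (any(truth == 1L))
          mean(pred[truth == 1L] == 1L) else NA_real_,
        specificity = if (any(truth == -1L))
          mean(pred[truth == -1L] == -1L) else NA_real_,
        accuracy = mean(pred == truth))
    })
    perFold <- do.call(rbind, perFold)
    folds <- data.frame(row = labeled, fold = foldOf,
                        confidence = heldConf, label = labels[labeled])
    structure(list(perFold = perFold,
                   meanAUC = mean(perFold$auc, na.rm = TRUE),
                   meanSensitivity = mean(perFold$sensitivity, na.rm = TRUE),
                   meanSpecificity = mean(perFold$specificity, na.rm = TRUE),
                   meanAccuracy = mean(perFold$accuracy),
                   folds = folds, seed = seed),
              class = "rgmCV")
  })
}

#' @export
print.rgmCV <- function(x, ...) {
  cat(sprintf(
    "RGM %d-fold CV: mean AUC = %.3f, sensitivity = %.3f, specificity = %.3f, accuracy = %.3f\n",
    nrow(x$perFold), x$meanAUC, x$meanSensitivity, x$meanSpecificity,
    x$meanAccuracy))
  invisible(x)
}

#' Null confidence distribution by label-permutation retraining
#'
#' Re-runs the full training pipeline (balancing, standardization, fitting,
#' prediction over all triplets) on label-permuted data `nPerm` times and
#' pools the resulting confidences, giving an empirical null for
#' [confidenceSignificance()]. When `features` and `allFeatures` index the
#' same triplet set, each permutation's own balanced training rows are
#' excluded from its contribution to the pool, so the null reflects
#' prediction, not memorization of the permuted labels.
#'
#' @inheritParams trainRGM
#' @param allFeatures feature matrix of every triplet to score under each
#'   null model.
#' @param nPerm number of label permutations, default 20.
#' @return matrix of null confidences, one row per `allFeatures` triplet
#'   and one column per permutation (`NA` where the triplet served in that
#'   permutation's balanced training set).
#' @export
nullConfidences <- function(features, labels, allFeatures, nPerm = 20,
                            seed = 1, cost = 1,
                            mapping = c("margin", "calibrated")) {
  mapping <- match.arg(mapping)
  withSeed(seed, {
    permSeeds <- sample.int(.Machine$integer.max %/% 2L, nPerm)
    cols <- lapply(seq_len(nPerm), function(b) {
      permLabels <- labels
      lab <- which(labels != 0L)
      permLabels[lab] <- sample(labels[lab])
      m <- trainRGM(features, permLabels, seed = permSeeds[b], cost = cost,
                    mapping = mapping)
      conf <- predictConfidences(m, allFeatures)
      if (nrow(features) == nrow(allFeatures)) conf[m$trainRows] <- NA
      conf
    })
    do.call(cbind, cols)
  })
}

#' Empirical significance of confidence levels
#'
#' Per-triplet two-sided empirical p-value against the label-permutation
#' null. Each triplet's observed confidence is first studentized by that
#' triplet's own null mean and SD across permutations (removing the
#' feature-driven component of the confidence scale, which permuted
#' classifiers reproduce); the standardized null values of all triplets
#' are pooled, and `p = (1 + #{|z_null| >= |z_obs|}) / (n_null + 1)`,
#' followed by Benjamini-Hochberg adjustment across triplets.
#'
#' @param confidences observed confidence vector.
#' @param nullConf null confidence matrix from [nullConfidences()]
#'   (triplets x permutations); a plain vector is treated as a pooled
#'   unstandardized null.
#' @param alpha FDR level for the significant set, default 0.05.
#' @return data.frame with `confidence`, `p`, `q`, `significant`.
#' @export
confidenceSignificance <- function(confidences, nullConf, alpha = 0.05) {
  if (length(nullConf) == 0L) stop("empty null confidence sample")
  if (is.matrix(nullConf)) {
    stopifnot(nrow(nullConf) == length(confidences))
    mu <- rowMeans(nullConf, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    sdv <- apply(nullConf, 1L, sd, na.rm = TRUE)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1e-8
    zObs <- (confidences - mu) / sdv
    zNull <- (nullConf - mu) / sdv
    nullAbs <- sort(abs(as.numeric(zNull[!is.na(zNull)])))
    obsAbs <- abs(zObs)
  } else {
    nullAbs <- sort(abs(nullConf))
    obsAbs <- abs(confidences)
  }
  nNull <- length(nullAbs)
  # #{|null| >= |obs|} via binary search on the sorted null magnitudes
  ge <- nNull - findInterval(obsAbs - 1e-12, nullAbs)
  p <- (1 + ge) / (nNull + 1)
  q <- bhFDR(p)
  data.frame(confidence = confidences, p = p, q = q,
             significant = q < alpha)
}
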