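# RGM classifier: features, labels, balanced training, CV, confidences,
# permutation significance.

test_that("feature construction matches a per-triplet recomputation", {
  st <- smallStudy(seed = 201, nSamples = 20)
  tri <- enumerateRGMTriplets(st$network, extendCompartments = TRUE)
  fb <- buildFeatures(st$network, st$cohort, tri, "cancer")
  expect_equal(ncol(fb$features), 14L)
  expect_equal(nrow(fb$features), nrow(fb$triplets))

  idx <- stratumSamples(st$cohort, "cancer")
  expr <- expressionMatrix(st$cohort)[, idx]
  rx <- reactions(st$network)
  gi <- networkGenes(st$network); mi <- networkMetabolites(st$network)
  rm_ <- reactionMetaboliteLinks(st$network)
  set.seed(1)
  for (i in sample(nrow(fb$triplets), 25)) {
    t_ <- fb$triplets[i, ]
    rrow <- rx[rx$reaction_id == t_$reaction_id, ]
    rmr <- rm_[rm_$reaction_id == t_$reaction_id, ]
    g <- expr[t_$gene_id, ]
    expected <- c(
      rrow$network_index, rrow$pathway_id, rrow$delta_g0,
      as.numeric(rrow$reversible),
      gi$network_index[gi$gene_id == t_$gene_id],
      mean(g), var(g), min(g), max(g),
      mi$network_index[mi$metabolite_id == t_$metabolite_id],
      length(unique(rmr$metabolite_id)),
      sum(rmr$role == "substrate"), sum(rmr$role == "product"),
      as.numeric(t_$is_substrate))
    expect_equal(unname(fb$features[i, ]), expected, tolerance = 1e-12)
  }
  # constant-expression gene: f6 = f8 = f9, f7 = 0
  co2 <- st$cohort
  exprC <- expressionMatrix(co2)
  exprC[1, ] <- 5
  co2 <- GMCohort(exprC, metaboliteMatrix(co2), sampleData(co2))
  g1 <- rownames(exprC)[1]
  triG <- tri[tri$gene_id == g1, , drop = FALSE]
  if (nrow(triG) > 0) {
    fbc <- buildFeatures(st$network, co2, triG[1, , drop = FALSE])
    expect_equal(unname(fbc$features[1, 6:9]), c(5, 0, 5, 5))
  }
})

test_that("unmeasured genes are excluded and listed", {
  st <- smallStudy(seed = 211, nSamples = 12)
  tri <- enumerateRGMTriplets(st$network, extendCompartments = TRUE)
  expr <- expressionMatrix(st$cohort)
  co <- GMCohort(expr[-1, , drop = FALSE], metaboliteMatrix(st$cohort),
                 sampleData(st$cohort))
  fb <- buildFeatures(st$network, co, tri)
  dropped <- rownames(expr)[1]
  expect_true(all(fb$excluded$gene_id == dropped))
  expect_false(dropped %in% fb$triplets$gene_id)
})

test_that("labels follow significance and correlation sign", {
  at <- data.frame(gene_id = c("g1", "g2", "g3"),
                   metabolite_id = c("m1", "m2", "m3"),
                   rho = c(0.8, -0.6, 0.9), p = c(1e-4, 0.01, 0.1),
                   q = c(0.001, 0.04, 0.2), stringsAsFactors = FALSE)
  tri <- data.frame(
    reaction_id = "R", gene_id = c("g1", "g2", "g3", "g1", "gX"),
    metabolite_id = c("m1", "m2", "m3", "m1", "mX"),
    is_substrate = FALSE, stringsAsFactors = FALSE)
  expect_equal(buildLabels(at, tri), c(1L, -1L, 0L, 1L, 0L))
})

test_that("training balances classes and separates a separable toy", {
  set.seed(5)
  X <- matrix(rnorm(120 * 14), 120, 14,
              dimnames = list(NULL, paste0("f", 1:14)))
  # a wide margin on f3 makes the problem cleanly separable
  X[, 3] <- sample(c(runif(60, 0.5, 2), runif(60, -2, -0.5)))
  labels <- ifelse(X[, 3] > 0, 1L, -1L)
  labels[sample(120, 30)] <- 0L  # unlabeled rows are ignored
  m <- trainRGM(X, labels, seed = 2)
  expect_equal(m$nPerClass, min(table(labels[labels != 0])))
  expect_setequal(unique(labels[m$trainRows]), c(-1L, 1L))
  expect_equal(sum(labels[m$trainRows] == 1), sum(labels[m$trainRows] == -1))
  conf <- predictConfidences(m, X)
  lab <- labels != 0
  expect_equal(mean(sign(conf[lab]) == labels[lab]), 1)
  expect_true(all(conf >= -1 & conf <= 1))
  expect_error(trainRGM(X, rep(1L, 120), seed = 1), "nonempty")
  expect_error(predictConfidences(m, X[, 1:5]), "mismatch")
})

test_that("null labels give chance-level cross-validation", {
  set.seed(6)
  X <- matrix(rnorm(80 * 14), 80, 14)
  aucs <- vapply(1:20, function(s) {
    labels <- sample(c(rep(1L, 25), rep(-1L, 25), rep(0L, 30)))
    crossValidate(X, labels, k = 5, seed = s)$meanAUC
  }, 0)
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("cross-validation is leakage-free, stratified and deterministic", {
  st <- smallStudy(seed = 221, nSamples = 30,
                   couplingFraction = c(noncancerous = 0.05, cancer = 0.25))
  at <- spearmanTable(st$cohort, st$pairs, "cancer")
  tri <- enumerateRGMTriplets(st$network, extendCompartments = TRUE)
  fb <- buildFeatures(st$network, st$cohort, tri, "cancer")
  labels <- buildLabels(at, fb$triplets)
  cv1 <- crossValidate(fb$features, labels, k = 5, seed = 3)
  cv2 <- crossValidate(fb$features, labels, k = 5, seed = 3)
  expect_identical(cv1$perFold, cv2$perFold)
  # folds partition the labeled set, stratified by label
  expect_setequal(cv1$folds$row, which(labels != 0))
  expect_equal(sort(unique(cv1$folds$fold)), 1:5)
  # permuting unlabeled rows leaves the result unchanged
  unl <- which(labels == 0)
  perm <- seq_len(nrow(fb$features))
  perm[unl] <- sample(unl)
  cv3 <- crossValidate(fb$features[perm, ], labels[perm], k = 5, seed = 3)
  expect_equal(cv3$perFold, cv1$perFold)
  expect_error(crossValidate(fb$features[1:4, ], c(1L, -1L, 0L, 0L), k = 5),
               "fewer")
})

test_that("AUC equals concordant-pair counting on small labeled sets", {
  # perfectly ordered confidences give AUC 1
  expect_equal(metacoupler:::aucScore(c(0.9, 0.7, -0.2, -0.8),
                                      c(TRUE, TRUE, FALSE, FALSE)), 1)
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(4:10, 1)
    scores <- round(rnorm(n), 1)  # rounding makes ties likely
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(metacoupler:::aucScore(scores, pos),
                 oracleAUC(scores, pos), tolerance = 1e-12)
  }
})

test_that("confidence significance has an exact add-one floor and null mean", {
  # vector null (pooled, unstandardized path)
  nullV <- seq(-0.999, 0.999, length.out = 999)
  res <- confidenceSignificance(c(0, 1), nullV)
  expect_equal(res$p[2], 1 / 1000)   # beyond all null values
  expect_gt(res$p[1], 0.9)           # center of a symmetric null

  # matrix null: studentized; observed equal to its own null mean -> p ~ 1
  set.seed(9)
  M <- matrix(rnorm(50 * 40, mean = 2), 50, 40)
  res2 <- confidenceSignificance(rowMeans(M), M)
  expect_true(all(res2$p > 0.5))
  expect_error(confidenceSignificance(1, numeric(0)), "empty")
})

test_that("significant confidences recover planted couplings", {
  st <- smallStudy(seed = 231, nSamples = 60,
                   couplingFraction = c(noncancerous = 0, cancer = 0.2),
                   strengthRange = c(0.8, 0.8))
  at <- spearmanTable(st$cohort, st$pairs, "cancer")
  tri <- enumerateRGMTriplets(st$network, extendCompartments = TRUE)
  fb <- buildFeatures(st$network, st$cohort, tri, "cancer")
  labels <- buildLabels(at, fb$triplets)
  m <- trainRGM(fb$features, labels, seed = 4)
  conf <- predictConfidences(m, fb$features, fb$triplets)
  nullC <- nullConfidences(fb$features, labels, fb$features, nPerm = 20,
                           seed = 5)
  expect_equal(dim(nullC), c(nrow(fb$features), 20L))
  sig <- confidenceSignificance(conf$confidence, nullC)
  key <- paste(st$truth$coupledPairs$gene_id,
               st$truth$coupledPairs$metabolite_id)
  planted <- paste(fb$triplets$gene_id, fb$triplets$metabolite_id) %in% key
  # most significant calls lie on planted pairs
  expect_gt(sum(sig$significant), 0)
  expect_gte(mean(planted[sig$significant]), 0.5)
})

test_that("confidences are deterministic under a fixed seed", {
  st <- smallStudy(seed = 241, nSamples = 25,
                   couplingFraction = c(noncancerous = 0.05, cancer = 0.25))
  at <- spearmanTable(st$cohort, st$pairs, "cancer")
  tri <- enumerateRGMTriplets(st$network, extendCompartments = TRUE)
  fb <- buildFeatures(st$network, st$cohort, tri, "cancer")
  labels <- buildLabels(at, fb$triplets)
  m1 <- trainRGM(fb$features, labels, seed = 11)
  m2 <- trainRGM(fb$features, labels, seed = 11)
  expect_identical(predictConfidences(m1, fb$features),
                   predictConfidences(m2, fb$features))
})
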