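# Metabolite-level regression: extreme-RGM selection, 28-feature
# instances, pooled OLS, prediction and evaluation.

mkConf <- function(reaction, gene, met, conf) {
  data.frame(reaction_id = reaction, gene_id = gene, metabolite_id = met,
             is_substrate = FALSE, confidence = conf,
             stringsAsFactors = FALSE)
}

test_that("selection takes the extremes with deterministic tie-breaks", {
  net <- generateNetwork(20, 30, 15, 2, seed = 7)
  tri <- enumerateRGMTriplets(net, extendCompartments = TRUE)
  m1 <- tri$metabolite_id[1]
  sub <- tri[tri$metabolite_id == m1, ][1:3, ]
  ct <- mkConf(sub$reaction_id, sub$gene_id, m1, c(0.9, -0.8, 0.1))
  sel <- selectRGMExtremes(ct, net, threshold = 0.5)
  expect_equal(sel$selection$conf_plus, 0.9)
  expect_equal(sel$selection$conf_minus, -0.8)
  expect_equal(sel$selection$gene_plus, sub$gene_id[1])
  # below threshold -> excluded and listed
  ct2 <- ct; ct2$confidence <- c(0.4, -0.3, 0.1)
  sel2 <- selectRGMExtremes(ct2, net, threshold = 0.5)
  expect_equal(nrow(sel2$selection), 0L)
  expect_equal(sel2$excluded, m1)
})

test_that("selection equals a brute-force scan on a random table", {
  net <- generateNetwork(25, 40, 20, 3, seed = 17)
  tri <- enumerateRGMTriplets(net, extendCompartments = TRUE)
  set.seed(18)
  ct <- tri
  ct$confidence <- round(runif(nrow(ct), -1, 1), 2)  # ties likely
  sel <- selectRGMExtremes(ct, net, threshold = 0)
  rx <- reactions(net); gi <- networkGenes(net)
  for (i in seq_len(nrow(sel$selection))) {
    s <- sel$selection[i, ]
    rows <- ct[ct$metabolite_id == s$metabolite_id, ]
    expect_equal(s$conf_plus, max(rows$confidence))
    expect_equal(s$conf_minus, min(rows$confidence))
    # tie-break: smallest (reaction index, gene index) among the argmax
    best <- rows[rows$confidence == max(rows$confidence), ]
    ord <- order(rx$network_index[match(best$reaction_id, rx$reaction_id)],
                 gi$network_index[match(best$gene_id, gi$gene_id)])
    expect_equal(s$reaction_plus, best$reaction_id[ord[1]])
    expect_equal(s$gene_plus, best$gene_id[ord[1]])
  }
})

test_that("instances have the documented 28-column layout", {
  st <- smallStudy(seed = 401, nSamples = 10)
  tri <- enumerateRGMTriplets(st$network, extendCompartments = TRUE)
  cyto <- rownames(metaboliteMatrix(st$cohort))
  ct <- tri[tri$metabolite_id %in% cyto, ]
  set.seed(2)
  ct$confidence <- runif(nrow(ct), -1, 1)
  sel <- selectRGMExtremes(ct, st$network, threshold = 0)
  sel$selection <- head(sel$selection, 10)
  inst <- buildInstances(sel$selection, st$cohort, st$network)
  nS <- ncol(expressionMatrix(st$cohort))
  expect_equal(dim(inst$X), c(10 * nS, 28L))
  expect_equal(colnames(inst$X), c(paste0("p", 1:14), paste0("n", 1:14)))
  expect_equal(nrow(inst$meta), 10L * nS)

  # the per-sample slots are the selected genes' expression
  expr <- expressionMatrix(st$cohort)
  i <- 5L
  s <- sel$selection[1, ]
  expect_equal(unname(inst$X[i, "p6"]),
               unname(expr[s$gene_plus, inst$meta$sample_id[i]]))
  expect_equal(unname(inst$X[i, "n6"]),
               unname(expr[s$gene_minus, inst$meta$sample_id[i]]))
  # two samples differ only in the f6 slots (plus block vs minus block)
  d <- which(inst$X[1, ] != inst$X[2, ])
  expect_true(all(colnames(inst$X)[d] %in% c("p6", "n6")))
  # summary mode keeps features constant across samples
  instS <- buildInstances(sel$selection, st$cohort, st$network,
                          f6Mode = "summary")
  expect_equal(instS$X[1, ], instS$X[2, ])
})

test_that("log z-scoring handles nonpositive values with a pseudo-offset", {
  M <- rbind(a = c(1, 2, 4, 8), b = c(0, 1, 3, 7))
  lz <- logZScoreMetabolites(M)
  expect_equal(dim(lz$z), dim(M))
  expect_equal(unname(rowMeans(lz$z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(lz$z, 1, sd)), c(1, 1), tolerance = 1e-12)
  # row b used offset = half its minimum positive value
  expect_equal(unname(lz$z["b", ]),
               unname(scale(log(c(0, 1, 3, 7) + 0.5))[, 1]),
               tolerance = 1e-12)
})

test_that("the pooled OLS fit matches the normal equations exactly", {
  set.seed(21)
  X <- matrix(rnorm(60 * 5), 60, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  beta <- c(2, -1, 0.5, 0, 3, 1.5)
  y <- cbind(1, X) %*% beta + rnorm(60, sd = 0.1)
  fit <- fitMetaboliteRegressor(X, as.numeric(y))
  expect_equal(unname(fit$coef), oracleOLS(X, as.numeric(y)),
               tolerance = 1e-8)
  # exact linear targets -> zero residuals
  y0 <- as.numeric(cbind(1, X) %*% beta)
  fit0 <- fitMetaboliteRegressor(X, y0)
  pred <- as.numeric(cbind(1, X) %*% fit0$coef)
  expect_lt(max(abs(pred - y0)), 1e-8)
  # rank-deficient design falls back to the pseudoinverse with a warning
  Xd <- cbind(X, X[, 1])
  expect_warning(fitMetaboliteRegressor(Xd, y0), "rank-deficient")
})

test_that("pure-noise targets give near-zero out-of-sample correlation", {
  set.seed(22)
  rhos <- vapply(1:20, function(s) {
    X <- matrix(rnorm(80 * 6), 80, 6)
    y <- rnorm(80)
    fit <- fitMetaboliteRegressor(X[1:40, ], y[1:40])
    yhat <- as.numeric(cbind(1, X[41:80, ]) %*% fit$coef)
    spearmanRho(yhat, y[41:80])$rho
  }, 0)
  expect_lt(mean(abs(rhos)), 0.15)
})

test_that("prediction is a pure function of instances, order-invariant", {
  set.seed(23)
  X <- matrix(rnorm(40 * 28), 40, 28,
              dimnames = list(NULL, c(paste0("p", 1:14), paste0("n", 1:14))))
  meta <- data.frame(metabolite_id = rep(paste0("m", 1:4), each = 10),
                     sample_id = rep(paste0("s", 1:10), 4),
                     stringsAsFactors = FALSE)
  model <- structure(list(coef = setNames(rnorm(29),
                                          c("(Intercept)", colnames(X)))),
                     class = "metRegressor")
  P1 <- predictMetabolites(model, list(X = X, meta = meta))
  perm <- sample(40)
  P2 <- predictMetabolites(model, list(X = X[perm, ], meta = meta[perm, ]))
  expect_equal(P1, P2[rownames(P1), colnames(P1)])
  expect_error(predictMetabolites(model, list(X = X[, 1:10], meta = meta)),
               "mismatch")
})

test_that("evaluation is exact on identity and sign-flipped predictions", {
  set.seed(24)
  measured <- matrix(rexp(6 * 12), 6, 12,
                     dimnames = list(paste0("m", 1:6), paste0("s", 1:12)))
  z <- logZScoreMetabolites(measured)$z
  ev <- evaluatePredictions(z, measured)
  expect_equal(ev$overall$rho, 1)
  expect_true(all(ev$perMetabolite$rho == 1))
  expect_true(all(ev$perSample$rho == 1))
  evNeg <- evaluatePredictions(-z, measured)
  expect_equal(evNeg$overall$rho, -1)
  expect_true(all(evNeg$perMetabolite$rho == -1))
  # per-metabolite rho is invariant to monotone rescaling of predictions
  ev2 <- evaluatePredictions(exp(2 * z), measured)
  expect_equal(ev2$perMetabolite$rho, ev$perMetabolite$rho)
})

test_that("noiseless planted linear couplings are recovered rank-exactly", {
  # measured metabolite is an exact monotone function of the selected
  # gene's expression; held-out per-metabolite correlation must be 1
  net <- generateNetwork(20, 30, 15, 2, seed = 31)
  tri <- enumerateRGMTriplets(net, extendCompartments = TRUE)
  genes <- networkGenes(net)$gene_id
  nS <- 30
  set.seed(32)
  expr <- matrix(rnorm(length(genes) * nS, 8, 1), length(genes), nS,
                 dimnames = list(genes, sprintf("s%02d", 1:nS)))
  mets <- unique(tri$metabolite_id)[1:5]
  sel <- do.call(rbind, lapply(mets, function(m) {
    rows <- tri[tri$metabolite_id == m, ]
    data.frame(metabolite_id = m,
               gene_plus = rows$gene_id[1], reaction_plus = rows$reaction_id[1],
               conf_plus = 0.9,
               gene_minus = rows$gene_id[nrow(rows)],
               reaction_minus = rows$reaction_id[nrow(rows)],
               conf_minus = -0.9, stringsAsFactors = FALSE)
  }))
  dummyMet <- matrix(1, nrow(sel), nS,
                     dimnames = list(sel$metabolite_id, colnames(expr)))
  co <- GMCohort(expr, dummyMet,
                 data.frame(condition = rep(c("noncancerous", "cancer"),
                                            each = nS / 2),
                            row.names = colnames(expr)))
  inst <- buildInstances(sel, co, net)
  # the true level is an exact linear function of the instance features
  y <- as.numeric(2 * inst$X[, "p6"] - inst$X[, "n6"] +
                    0.05 * inst$X[, "p3"])
  metab <- matrix(NA_real_, nrow(sel), nS,
                  dimnames = list(sel$metabolite_id, colnames(expr)))
  metab[cbind(match(inst$meta$metabolite_id, rownames(metab)),
              match(inst$meta$sample_id, colnames(metab)))] <- exp(y / 8)
  train <- inst$meta$sample_id %in% colnames(expr)[1:20]
  fit <- suppressWarnings(fitMetaboliteRegressor(inst$X[train, ], y[train]))
  pred <- predictMetabolites(fit, inst)
  held <- colnames(expr)[21:30]
  ev <- evaluatePredictions(pred[, held], metab[, held], sel)
  expect_equal(ev$perMetabolite$rho, rep(1, nrow(sel)), tolerance = 1e-12)
})
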