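# Pathway analyses: regulated reactions, prediction-based enrichment,
# raw-data shift, cross-dataset agreement.

test_that("a reaction is regulated iff any of its triplets is significant", {
  tri <- data.frame(
    reaction_id = rep(c("R1", "R2"), c(6, 4)),
    gene_id = "g", metabolite_id = paste0("m", 1:10),
    is_substrate = FALSE, stringsAsFactors = FALSE)
  sig <- data.frame(confidence = rnorm(10), p = 0.5, q = 0.5,
                    significant = c(TRUE, rep(FALSE, 9)))
  expect_equal(regulatedReactions(sig, tri), "R1")
  sig$significant <- FALSE
  expect_length(regulatedReactions(sig, tri), 0L)
  # brute-force scan oracle on random flags
  set.seed(3)
  for (rep in 1:5) {
    sig$significant <- runif(10) < 0.3
    reg <- regulatedReactions(sig, tri)
    expected <- sort(unique(tri$reaction_id[sig$significant]))
    expect_equal(reg, expected)
  }
})

test_that("regulated sets are monotone in alpha", {
  set.seed(4)
  tri <- data.frame(reaction_id = paste0("R", sample(8, 40, TRUE)),
                    gene_id = "g", metabolite_id = paste0("m", 1:40),
                    is_substrate = FALSE, stringsAsFactors = FALSE)
  conf <- rnorm(40)
  nullM <- matrix(rnorm(40 * 25), 40, 25)
  loose <- regulatedReactions(
    confidenceSignificance(conf, nullM, alpha = 0.3), tri)
  strict <- regulatedReactions(
    confidenceSignificance(conf, nullM, alpha = 0.05), tri)
  expect_true(all(strict %in% loose))
})

test_that("prediction enrichment matches the exact hypergeometric tail", {
  net <- generateNetwork(30, 50, 25, 3, seed = 41)
  tri <- enumerateRGMTriplets(net, extendCompartments = TRUE)
  rx <- reactions(net)
  hot <- rx$reaction_id[rx$pathway == "P01"]
  hot <- intersect(hot, tri$reaction_id)
  pe <- predictionEnrichment(list(cancer = hot), net, tri)
  popRx <- unique(tri$reaction_id)
  row <- pe[pe$pathway == "P01", ]
  expect_equal(row$n_regulated, length(hot))
  expect_equal(row$p,
               oracleHyperUpper(length(hot), length(hot), length(popRx),
                                row$n_total),
               tolerance = 1e-12)
  # every reaction regulated -> all p = 1
  peAll <- predictionEnrichment(list(cancer = popRx), net, tri)
  expect_true(all(peAll$p == 1))
  expect_true(all(peAll$q >= peAll$p - 1e-12))
})

test_that("the raw shift test enforces the minimum-pairs rule exactly", {
  net <- readNetwork(toyNetworkFile())
  pairs <- connectedGMPairs(net)
  mk <- function(p) data.frame(gene_id = pairs$gene_id,
                               metabolite_id = pairs$metabolite_id,
                               stratum = "x", rho = 0, p = p, q = p,
                               stringsAsFactors = FALSE)
  # 8 pairs in total: every pathway has < 9 measured pairs
  expect_message(
    out <- rawGMShift(mk(runif(8)), mk(runif(8)), net, pairs, minPairs = 9),
    "no pathway")
  expect_equal(nrow(out), 0L)
  # with the bar at the observed count the pathway is eligible
  set.seed(5)
  pn <- runif(8); pc <- runif(8)
  out2 <- rawGMShift(mk(pn), mk(pc), net, pairs, minPairs = 5)
  expect_gt(nrow(out2), 0L)
  expect_true(all(out2$n_pairs >= 5))
})

test_that("the raw shift p-value is exact for small separated pathways", {
  net <- readNetwork(toyNetworkFile())
  pairs <- connectedGMPairs(net)
  # PW_B pairs get all-smaller cancer p-values
  mk <- function(p) data.frame(gene_id = pairs$gene_id,
                               metabolite_id = pairs$metabolite_id,
                               stratum = "x", rho = 0, p = p, q = p,
                               stringsAsFactors = FALSE)
  pn <- seq(0.5, 0.9, length.out = 8)
  pc <- seq(0.01, 0.05, length.out = 8)
  out <- rawGMShift(mk(pn), mk(pc), net, pairs, minPairs = 2)
  for (i in seq_len(nrow(out))) {
    member <- vapply(pairs$reaction_ids, function(rxs)
      out$pathway_id[i] %in%
        reactions(net)$pathway_id[match(rxs, reactions(net)$reaction_id)],
      TRUE)
    expect_equal(out$p[i],
                 oracleRankSumP(pn[member], pc[member], "two.sided"),
                 tolerance = 1e-12)
    expect_gt(out$median_diff[i], 0)
  }
  # identical p-value sets carry no shift evidence
  same <- rawGMShift(mk(pn), mk(pn), net, pairs, minPairs = 2)
  expect_true(all(same$p == 1))
})

test_that("hot-pathway planting is detected condition-specifically", {
  # cancer-only design: couplings confined to the hot pathway exist only
  # in the cancer condition
  hits <- vapply(1:5, function(s) {
    net <- generateNetwork(100, 250, 120, 4, seed = 500 + s,
                           otherCompartmentFraction = 0.6)
    om <- suppressWarnings(generateOmics(
      net, 60, couplingFraction = c(noncancerous = 0, cancer = 0.25),
      strengthRange = c(0.8, 0.8), hotPathway = "P01", seed = 600 + s))
    mets <- networkMetabolites(net)
    cyto <- mets$metabolite_id[mets$compartment == "c"]
    co <- GMCohort(expressionMatrix(om$cohort),
                   metaboliteMatrix(om$cohort)[cyto, ], sampleData(om$cohort))
    pairs <- connectedGMPairs(net, "c")
    tri <- enumerateRGMTriplets(net, extendCompartments = TRUE)
    reg <- lapply(c(noncancerous = "noncancerous", cancer = "cancer"),
                  function(str) {
      at <- spearmanTable(co, pairs, str)
      fb <- buildFeatures(net, co, tri, str)
      labels <- buildLabels(at, fb$triplets)
      if (sum(labels == 1) < 5 || sum(labels == -1) < 5)
        return(character(0))
      m <- trainRGM(fb$features, labels, seed = 7)
      conf <- predictConfidences(m, fb$features)
      nullC <- nullConfidences(fb$features, labels, fb$features,
                               nPerm = 15, seed = 8)
      regulatedReactions(confidenceSignificance(conf, nullC), fb$triplets)
    })
    pe <- predictionEnrichment(reg, net, tri)
    canc <- pe[pe$condition == "cancer", ]
    nc <- pe[pe$condition == "noncancerous", ]
    isTRUE(canc$q[canc$pathway == "P01"] < 0.05) &&
      !isTRUE(nc$q[nc$pathway == "P01"] < 0.05)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("cross-dataset agreement is exact on identical tables and null", {
  tab <- data.frame(pathway_id = 1:8, p = c(0.001, 0.02, 0.03, 0.04,
                                            0.2, 0.5, 0.7, 0.9))
  res <- crossDatasetAgreement(tab, tab)
  expect_equal(res$rho, 1)
  expect_equal(res$n, 4L)  # pathways significant in either table
  # fewer than 4 shared significant pathways -> flagged
  tabSmall <- tab[1:3, ]
  expect_true(crossDatasetAgreement(tabSmall, tabSmall)$flagged)
  # independent tables: small |rho| on average over seeds
  set.seed(9)
  rhos <- vapply(1:20, function(i) {
    a <- data.frame(pathway_id = 1:12, p = runif(12))
    b <- data.frame(pathway_id = 1:12, p = runif(12))
    r <- crossDatasetAgreement(a, b)
    if (is.na(r$rho)) 0 else r$rho
  }, 0)
  expect_lt(abs(mean(rhos)), 0.3)
})

test_that("shared planted pathways give correlated enrichment profiles", {
  agree <- vapply(1:5, function(s) {
    net <- generateNetwork(100, 250, 120, 8, seed = 700 + s,
                           otherCompartmentFraction = 0.6)
    mkTab <- function(seed) {
      om <- suppressWarnings(generateOmics(
        net, 60, couplingFraction = c(noncancerous = 0, cancer = 0.25),
        strengthRange = c(0.8, 0.8), hotPathway = c("P01", "P02", "P03"),
        seed = seed))
      mets <- networkMetabolites(net)
      cyto <- mets$metabolite_id[mets$compartment == "c"]
      co <- GMCohort(expressionMatrix(om$cohort),
                     metaboliteMatrix(om$cohort)[cyto, ],
                     sampleData(om$cohort))
      pairs <- connectedGMPairs(net, "c")
      tri <- enumerateRGMTriplets(net, extendCompartments = TRUE)
      at <- spearmanTable(co, pairs, "cancer")
      fb <- buildFeatures(net, co, tri, "cancer")
      labels <- buildLabels(at, fb$triplets)
      m <- trainRGM(fb$features, labels, seed = 7)
      conf <- predictConfidences(m, fb$features)
      nullC <- nullConfidences(fb$features, labels, fb$features,
                               nPerm = 15, seed = 8)
      reg <- regulatedReactions(confidenceSignificance(conf, nullC),
                                fb$triplets)
      predictionEnrichment(list(cancer = reg), net, tri)
    }
    # two cohorts over the same network and hot pathway; the profile over
    # all shared pathways is compared
    r <- crossDatasetAgreement(mkTab(1000 + s), mkTab(2000 + s),
                               sigLevel = 1)
    !is.na(r$rho) && r$rho > 0.5
  }, TRUE)
  expect_gte(mean(agree), 0.6)
})
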