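# End-to-end orchestration: generate/load -> associate -> classify ->
# graph -> predict-metabolites -> pathways -> clinical, with seeded
# determinism and per-stage artifacts.

#' Default pipeline configuration
#'
#' Returns the configuration list [runPipeline()] starts from. Thresholds
#' carry the pipeline's standard operating points: `alpha = 0.05` (FDR),
#' `nPerm = 1000` permutations, `kFolds = 5`, `confidenceThreshold = 0.5`,
#' `degreeThreshold = 4`, `minPathwayPairs = 10`, and `nNullPerm = 20`
#' label-permutation retrainings for confidence significance. The
#' `generate` block describes the synthetic study drawn when no input
#' files are configured.
#'
#' @return a named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    alpha = 0.05, nPerm = 1000, kFolds = 5, confidenceThreshold = 0.5,
    degreeThreshold = 4, minPathwayPairs = 10, nNullPerm = 20,
    svmCost = 1, confidenceMapping = "margin", f6Mode = "per-sample",
    expressionQuantile = 0.75,
    files = NULL,  # list(network=, cohortDir=) to load instead of generate
    generate = list(nReactions = 60, nGenes = 150, nMetabolites = 80,
                    nPathways = 4, nSamplesPerCondition = 40,
                    otherCompartmentFraction = 0.5,
                    couplingFraction = c(noncancerous = 0.1, cancer = 0.4),
                    strengthRange = c(0.5, 0.9), varMultiplier = 2,
                    hotPathway = "P01",
                    hazardCoef = log(2), nHazardMetabolites = 1,
                    erShift = 2)
  )
}

readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  base <- defaultPipelineConfig()
  base[names(config)] <- config
  if (!is.null(config$generate)) {
    gen <- defaultPipelineConfig()$generate
    gen[names(config$generate)] <- config$generate
    base$generate <- gen
  }
  cf <- base$generate$couplingFraction
  if (!is.null(names(cf))) cf <- unlist(cf)
  base$generate$couplingFraction <-
    setNames(as.numeric(cf), c("noncancerous", "cancer"))
  base
}

logStage <- function(con, stage, ...) {
  entry <- c(list(stage = stage, time = format(Sys.time(), "%H:%M:%S")),
             list(...))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
}

#' Run the full coupling pipeline
#'
#' Executes the stages in order -- synthetic generation (or file loading),
#' per-stratum association tables and permutation tests, RGM classification
#' with cross-validation and confidence significance, the bipartite graph,
#' extreme-RGM selection plus pooled regression of metabolite levels,
#' pathway enrichment (prediction-based and raw shift), and the clinical
#' survival/ER screens -- writing each stage's artifacts into `outDir`.
#' Every source of randomness derives from `seed`, so reruns are
#' byte-identical.
#'
#' @param config a configuration list (see [defaultPipelineConfig()]) or
#'   the path to a YAML file with overrides.
#' @param outDir output directory (created).
#' @param seed integer master seed.
#' @return invisibly, a list with the in-memory stage results (`network`,
#'   `cohort`, `truth`, `assoc`, `permTests`, `cv`, `confidence`,
#'   `graphs`, `selection`, `predicted`, `evaluation`, `pathways`,
#'   `clinical`).
#' @export
runPipeline <- function(config = list(), outDir, seed = 1) {
  cfg <- readPipelineConfig(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logCon <- file(file.path(outDir, "log.jsonl"), open = "wt")
  on.exit(close(logCon))
  jsonlite::write_json(c(cfg, list(seed = seed)),
                       file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  seeds <- withSeed(seed, sample.int(2^30, 12))

  # ---- stage: generate / load --------------------------------------------
  truth <- NULL
  if (is.null(cfg$files)) {
    g <- cfg$generate
    network <- generateNetwork(g$nReactions, g$nGenes, g$nMetabolites,
                               g$nPathways, seed = seeds[1],
                               otherCompartmentFraction =
                                 g$otherCompartmentFraction)
    hazard <- NULL; erLink <- NULL
    metsTab <- networkMetabolites(network)
    metIds <- metsTab$metabolite_id[metsTab$compartment == "c"]
    if (g$nHazardMetabolites > 0)
      hazard <- data.frame(
        metabolite_id = metIds[seq_len(g$nHazardMetabolites)],
        coef = g$hazardCoef, stringsAsFactors = FALSE)
    if (!is.null(g$erShift))
      erLink <- list(metabolite_id = metIds[length(metIds)],
                     shift = g$erShift)
    om <- generateOmics(network, g$nSamplesPerCondition,
                        g$couplingFraction, g$strengthRange,
                        varMultiplier = g$varMultiplier,
                        hotPathway = g$hotPathway, hazardLinks = hazard,
                        erLink = erLink, seed = seeds[2])
    cohort <- generateClinical(om$cohort, om$truth, seed = seeds[3])
    # only the cytoplasmic layer is measured, as in targeted metabolomics
    cohort <- GMCohort(expressionMatrix(cohort),
                       metaboliteMatrix(cohort)[metIds, , drop = FALSE],
                       sampleData(cohort))
    truth <- om$truth
    writeNetwork(network, file.path(outDir, "network.tsv"))
    writeCohort(cohort, outDir)
    writeTruth(truth, file.path(outDir, "truth.json"))
    logStage(logCon, "generate",
             reactions = nrow(reactions(network)),
             planted = if (is.null(truth$coupledPairs)) 0 else
               nrow(truth$coupledPairs))
  } else {
    network <- readNetwork(cfg$files$network)
    cohort <- readCohort(cfg$files$cohortDir)
    logStage(logCon, "load", reactions = nrow(reactions(network)))
  }

  # ---- stage: associate ---------------------------------------------------
  pairs <- connectedGMPairs(network, compartment = "c")
  measured <- pairs$gene_id %in% rownames(expressionMatrix(cohort)) &
    pairs$metabolite_id %in% rownames(metaboliteMatrix(cohort))
  pairs <- pairs[measured, , drop = FALSE]
  strata <- c("all", "noncancerous", "cancer")
  assoc <- lapply(setNames(strata, strata), function(s)
    spearmanTable(cohort, pairs, s))
  for (s in strata)
    write.table(assoc[[s]][, names(assoc[[s]]) != "reaction_ids"],
                file.path(outDir, paste0("association_", s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  permTests <- lapply(setNames(strata, strata), function(s)
    couplingPermutationTest(cohort, pairs, s, alpha = cfg$alpha,
                            nPerm = cfg$nPerm, seed = seeds[4]))
  stats <- lapply(permTests, function(x)
    list(n_sig_real = x$n_sig_real, empiric_p = x$empiric_p, r = x$r,
         n_perm = x$n_perm))
  jsonlite::write_json(stats, file.path(outDir, "association_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  logStage(logCon, "associate", pairs = nrow(pairs))

  # ---- stage: classify ----------------------------------------------------
  triplets <- enumerateRGMTriplets(network, extendCompartments = TRUE)
  classify <- lapply(setNames(strata, strata), function(s) {
    fb <- buildFeatures(network, cohort, triplets, s)
    labels <- buildLabels(assoc[[s]], fb$triplets, cfg$alpha)
    cv <- crossValidate(fb$features, labels, k = cfg$kFolds,
                        seed = seeds[5], cost = cfg$svmCost,
                        mapping = cfg$confidenceMapping)
    model <- trainRGM(fb$features, labels, seed = seeds[6],
                      cost = cfg$svmCost, mapping = cfg$confidenceMapping)
    conf <- predictConfidences(model, fb$features, fb$triplets)
    nullC <- nullConfidences(fb$features, labels, fb$features,
                             nPerm = cfg$nNullPerm, seed = seeds[7],
                             cost = cfg$svmCost,
                             mapping = cfg$confidenceMapping)
    sig <- confidenceSignificance(conf$confidence, nullC, cfg$alpha)
    conf$q <- sig$q; conf$significant <- sig$significant
    conf$label <- labels
    write.table(conf, file.path(outDir, paste0("confidence_", s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(meanAUC = cv$meanAUC, meanSensitivity = cv$meanSensitivity,
           meanSpecificity = cv$meanSpecificity,
           meanAccuracy = cv$meanAccuracy),
      file.path(outDir, paste0("cv_", s, ".json")),
      auto_unbox = TRUE, digits = NA)
    list(features = fb, labels = labels, cv = cv, model = model,
         confidence = conf, sig = sig)
  })
  logStage(logCon, "classify",
           meanAUC_all = classify$all$cv$meanAUC)

  # ---- stage: graph -------------------------------------------------------
  graphs <- lapply(setNames(c("noncancerous", "cancer"),
                            c("noncancerous", "cancer")), function(s) {
    gr <- buildGMGraph(assoc[[s]], cfg$alpha)
    writeGMGraph(gr, file.path(outDir, paste0("graph_", s, ".graphml")))
    enr <- hubPathwayEnrichment(gr, network, cfg$degreeThreshold)
    write.table(enr, file.path(outDir, paste0("hub_enrichment_", s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gr
  })
  logStage(logCon, "graph",
           edges_cancer = igraph::ecount(graphs$cancer),
           edges_noncancerous = igraph::ecount(graphs$noncancerous))

  # ---- stage: predict-metabolites ----------------------------------------
  sel <- selectRGMExtremes(classify$all$confidence, network,
                           cfg$confidenceThreshold)
  inst <- buildInstances(sel$selection, cohort, network, cfg$f6Mode)
  lz <- logZScoreMetabolites(metaboliteMatrix(cohort))
  measuredTarget <- inst$meta$metabolite_id %in% rownames(lz$z)
  y <- lz$z[cbind(match(inst$meta$metabolite_id[measuredTarget],
                        rownames(lz$z)),
                  match(inst$meta$sample_id[measuredTarget],
                        colnames(lz$z)))]
  model <- fitMetaboliteRegressor(inst$X[measuredTarget, , drop = FALSE], y)
  predicted <- predictMetabolites(model, inst)
  evaluation <- evaluatePredictions(predicted,
                                    metaboliteMatrix(cohort),
                                    sel$selection)
  write.table(data.frame(metabolite_id = rownames(predicted), predicted,
                         check.names = FALSE),
              file.path(outDir, "predicted_metabolites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(overall = evaluation$overall[c("rho", "p", "n")],
         metaCorrelation = evaluation$metaCorrelation[c("rho", "p")],
         nSignificantMetabolites =
           sum(evaluation$perMetabolite$q < cfg$alpha),
         nMetabolites = nrow(evaluation$perMetabolite)),
    file.path(outDir, "regression_evaluation.json"),
    auto_unbox = TRUE, digits = NA)
  logStage(logCon, "predict-metabolites",
           selected = nrow(sel$selection),
           overall_rho = evaluation$overall$rho)

  # ---- stage: pathways ----------------------------------------------------
  regulated <- lapply(
    setNames(c("noncancerous", "cancer"), c("noncancerous", "cancer")),
    function(s) regulatedReactions(classify[[s]]$sig,
                                   classify[[s]]$features$triplets))
  predEnr <- predictionEnrichment(regulated, network, triplets)
  write.table(predEnr, file.path(outDir, "pathway_prediction_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  shift <- rawGMShift(assoc$noncancerous, assoc$cancer, network, pairs,
                      cfg$minPathwayPairs)
  write.table(shift, file.path(outDir, "pathway_raw_shift.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  logStage(logCon, "pathways", eligible_shift_pathways = nrow(shift))

  # ---- stage: clinical ----------------------------------------------------
  clinical <- NULL
  sdat <- sampleData(cohort)
  if (any(is.finite(sdat$survival_time))) {
    screen <- survivalScreen(predicted, sdat, cfg$alpha)
    screen <- geneVsMetaboliteSurvival(screen, expressionMatrix(cohort),
                                       network, sdat)
    write.table(screen, file.path(outDir, "survival_screen.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    er <- NULL
    if (length(unique(sdat$er_status[!is.na(sdat$er_status)])) == 2L) {
      er <- erDifferential(predicted, sdat$er_status, cfg$alpha)
      write.table(er, file.path(outDir, "er_differential.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    clinical <- list(screen = screen, er = er)
    logStage(logCon, "clinical",
             significant_metabolites = sum(screen$significant))
  }

  invisible(list(network = network, cohort = cohort, truth = truth,
                 pairs = pairs, assoc = assoc, permTests = permTests,
                 classify = classify, graphs = graphs, selection = sel,
                 regressor = model, predicted = predicted,
                 evaluation = evaluation,
                 pathways = list(prediction = predEnr, shift = shift,
                                 regulated = regulated),
                 clinical = clinical, config = cfg, seed = seed))
}
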