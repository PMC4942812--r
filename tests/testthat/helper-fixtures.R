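# Shared fixtures, all built in code.

# a 3-reaction hand-written network table
toyNetworkFile <- function(dir = tempdir()) {
  tab <- data.frame(
    reaction_id = c("R1", "R2", "R3"),
    genes = c("g1;g2", "g2", "g3"),
    substrates = c("a[c]", "b[c]", "a[c];c[m]"),
    products = c("b[c]", "c[m]", "d[c]"),
    reversible = c(0L, 1L, 0L),
    delta_g0 = c(-5.2, 0.4, 12.1),
    pathway = c("PW_B", "PW_B", "PW_A"),
    stringsAsFactors = FALSE
  )
  path <- file.path(dir, paste0("toy-net-", basename(tempfile()), ".tsv"))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a cohort built directly from matrices (rows named, one condition block
# each); genes/mets default to simple names
toyCohort <- function(expr, metab, nNC = ncol(expr) %/% 2) {
  samples <- sprintf("s%02d", seq_len(ncol(expr)))
  colnames(expr) <- colnames(metab) <- samples
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("g%02d", seq_len(nrow(expr)))
  if (is.null(rownames(metab)))
    rownames(metab) <- sprintf("m%02d", seq_len(nrow(metab)))
  cond <- c(rep("noncancerous", nNC), rep("cancer", ncol(expr) - nNC))
  GMCohort(expr, metab, data.frame(condition = cond, row.names = samples))
}

# a small standard synthetic study reused by several module tests:
# sparse measured layer, couplings mostly in the cancer condition
smallStudy <- function(seed = 1, nSamples = 40,
                       couplingFraction = c(noncancerous = 0.05,
                                            cancer = 0.2),
                       strengthRange = c(0.6, 0.9), hotPathway = "P01",
                       ...) {
  net <- generateNetwork(60, 150, 80, 4, seed = seed,
                         otherCompartmentFraction = 0.5)
  om <- suppressWarnings(generateOmics(
    net, nSamples, couplingFraction = couplingFraction,
    strengthRange = strengthRange, hotPathway = hotPathway,
    seed = seed + 1000, ...))
  mets <- networkMetabolites(net)
  cyto <- mets$metabolite_id[mets$compartment == "c"]
  cohort <- GMCohort(expressionMatrix(om$cohort),
                     metaboliteMatrix(om$cohort)[cyto, , drop = FALSE],
                     sampleData(om$cohort))
  list(network = net, cohort = cohort, truth = om$truth,
       pairs = connectedGMPairs(net, "c"))
}
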