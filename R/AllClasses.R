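#' MetabolicNetwork: a genome-scale metabolic network container
#'
#' Holds reactions, genes and metabolites together with the two link tables
#' (reaction-gene and reaction-metabolite-role) that define which enzymes
#' catalyze which reactions and which metabolites they consume or produce.
#' Every entity class carries a deterministic `network_index` (1-based,
#' contiguous, assigned in lexicographic ID order) that downstream feature
#' construction uses as a categorical position proxy.
#'
#' Compartments are encoded as a suffix token on the metabolite ID
#' (`"glc[c]"` is cytoplasmic glucose); `"c"` denotes the cytoplasm.
#'
#' @slot reactions data.frame with columns `reaction_id`, `network_index`,
#'   `pathway` (label), `pathway_id` (integer code by first appearance),
#'   `delta_g0` (predicted standard Gibbs energy, kJ/mol), `reversible`
#'   (logical).
#' @slot genes data.frame with columns `gene_id`, `network_index`.
#' @slot metabolites data.frame with columns `metabolite_id`, `compartment`,
#'   `network_index`.
#' @slot reactionGenes data.frame with columns `reaction_id`, `gene_id`.
#' @slot reactionMetabolites data.frame with columns `reaction_id`,
#'   `metabolite_id`, `role` (`"substrate"` or `"product"`). A metabolite
#'   appearing in both roles of one reaction has two rows.
#'
#' @seealso [readNetwork()], [generateNetwork()], [connectedGMPairs()],
#'   [enumerateRGMTriplets()]
#' @export
setClass("MetabolicNetwork",
  representation(
    reactions           = "data.frame",
    genes               = "data.frame",
    metabolites         = "data.frame",
    reactionGenes       = "data.frame",
    reactionMetabolites = "data.frame"
  )
)

setValidity("MetabolicNetwork", function(object) {
  msgs <- character(0)
  rx <- object@reactions; gn <- object@genes; mb <- object@metabolites
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      msgs <<- c(msgs, sprintf("%s lacks column(s): %s", what,
                               paste(miss, collapse = ", ")))
  }
  need(rx, c("reaction_id", "network_index", "pathway", "pathway_id",
             "delta_g0", "reversible"), "reactions")
  need(gn, c("gene_id", "network_index"), "genes")
  need(mb, c("metabolite_id", "compartment", "network_index"), "metabolites")
  need(object@reactionGenes, c("reaction_id", "gene_id"), "reactionGenes")
  need(object@reactionMetabolites, c("reaction_id", "metabolite_id", "role"),
       "reactionMetabolites")
  if (length(msgs)) return(msgs)

  if (anyDuplicated(rx$reaction_id))
    msgs <- c(msgs, "duplicate reaction_id")
  if (anyDuplicated(gn$gene_id))
    msgs <- c(msgs, "duplicate gene_id")
  if (anyDuplicated(mb$metabolite_id))
    msgs <- c(msgs, "duplicate metabolite_id")
  contiguous <- function(ix) length(ix) == 0L ||
    identical(sort(as.integer(ix)), seq_len(length(ix)))
  if (!contiguous(rx$network_index) || !contiguous(gn$network_index) ||
      !contiguous(mb$network_index))
    msgs <- c(msgs, "network_index must be contiguous from 1 per entity class")

  dangling <- function(ids, universe) unique(ids[!(ids %in% universe)])
  dg <- dangling(object@reactionGenes$gene_id, gn$gene_id)
  if (length(dg))
    msgs <- c(msgs, sprintf("reactionGenes references unknown gene(s): %s",
                            paste(dg, collapse = ", ")))
  dm <- dangling(object@reactionMetabolites$metabolite_id, mb$metabolite_id)
  if (length(dm))
    msgs <- c(msgs, sprintf(
      "reactionMetabolites references unknown metabolite(s): %s",
      paste(dm, collapse = ", ")))
  dr <- dangling(c(object@reactionGenes$reaction_id,
                   object@reactionMetabolites$reaction_id), rx$reaction_id)
  if (length(dr))
    msgs <- c(msgs, sprintf("link tables reference unknown reaction(s): %s",
                            paste(dr, collapse = ", ")))
  if (!all(object@reactionMetabolites$role %in% c("substrate", "product")))
    msgs <- c(msgs, "role must be 'substrate' or 'product'")
  if (length(msgs)) msgs else TRUE
})

#' GMCohort: matched expression and metabolite profiles with sample metadata
#'
#' A two-assay cohort: a gene expression matrix (genes x samples, log scale)
#' and a metabolite abundance matrix (metabolites x samples, positive values
#' before any log transform), sharing one ordered sample axis described by
#' `sampleData`. The sample table always carries a `condition` column
#' (`"noncancerous"` / `"cancer"`); clinical columns (`survival_time` in
#' months, `event`, `er_status`) are `NA` until filled, e.g. by
#' [generateClinical()].
#'
#' @slot expression numeric matrix, genes x samples.
#' @slot metabolites numeric matrix, metabolites x samples.
#' @slot sampleData data.frame keyed by sample, rownames = sample IDs.
#'
#' @seealso [GMCohort()], [generateOmics()]
#' @export
setClass("GMCohort",
  representation(
    expression  = "matrix",
    metabolites = "matrix",
    sampleData  = "data.frame"
  )
)

setValidity("GMCohort", function(object) {
  msgs <- character(0)
  sn <- rownames(object@sampleData)
  if (is.null(sn)) msgs <- c(msgs, "sampleData must have sample rownames")
  if (!identical(colnames(object@expression), sn))
    msgs <- c(msgs, "expression columns must match sampleData rows")
  if (!identical(colnames(object@metabolites), sn))
    msgs <- c(msgs, "metabolite columns must match sampleData rows")
  if (!("condition" %in% names(object@sampleData)))
    msgs <- c(msgs, "sampleData must have a 'condition' column")
  if (is.null(rownames(object@expression)) ||
      anyDuplicated(rownames(object@expression)))
    msgs <- c(msgs, "expression must have unique gene rownames")
  if (is.null(rownames(object@metabolites)) ||
      anyDuplicated(rownames(object@metabolites)))
    msgs <- c(msgs, "metabolites must have unique metabolite rownames")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GMCohort
#'
#' @param expression genes x samples numeric matrix (log-scale expression).
#' @param metabolites metabolites x samples numeric matrix (abundances).
#' @param sampleData data.frame with rownames matching the shared sample
#'   axis; must contain a `condition` column. Missing clinical columns
#'   (`survival_time`, `event`, `er_status`) are added as `NA`.
#' @return a [GMCohort-class] object.
#' @export
GMCohort <- function(expression, metabolites, sampleData) {
  for (cl in c("survival_time", "event", "er_status"))
    if (!(cl %in% names(sampleData))) sampleData[[cl]] <- NA
  new("GMCohort", expression = expression, metabolites = metabolites,
      sampleData = sampleData)
}

setMethod("show", "MetabolicNetwork", function(object) {
  cat("MetabolicNetwork:",
      nrow(object@reactions), "reactions,",
      nrow(object@genes), "genes,",
      nrow(object@metabolites), "metabolites\n")
  cat("  compartments:", paste(sort(unique(object@metabolites$compartment)),
                               collapse = ", "), "\n")
  cat("  pathways:", length(unique(object@reactions$pathway_id)), "\n")
})

setMethod("show", "GMCohort", function(object) {
  cond <- table(object@sampleData$condition)
  cat("GMCohort:", nrow(object@expression), "genes x",
      ncol(object@expression), "samples;",
      nrow(object@metabolites), "metabolites\n")
  cat("  conditions:",
      paste(sprintf("%s=%d", names(cond), cond), collapse = ", "), "\n")
  cat("  clinical:",
      if (all(is.na(object@sampleData$survival_time))) "absent" else
        "survival + ER", "\n")
})

# ---- accessors ------------------------------------------------------------

#' @describeIn MetabolicNetwork-class reaction table accessor
#' @param object a `MetabolicNetwork` or `GMCohort`
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))
#' @export
setMethod("reactions", "MetabolicNetwork", function(object) object@reactions)

#' @describeIn MetabolicNetwork-class gene table accessor
#' @export
setGeneric("networkGenes", function(object) standardGeneric("networkGenes"))
#' @export
setMethod("networkGenes", "MetabolicNetwork",
          function(object) object@genes)

#' @describeIn MetabolicNetwork-class metabolite table accessor
#' @export
setGeneric("networkMetabolites",
           function(object) standardGeneric("networkMetabolites"))
#' @export
setMethod("networkMetabolites", "MetabolicNetwork",
          function(object) object@metabolites)

#' @describeIn MetabolicNetwork-class reaction-gene link table
#' @export
setGeneric("reactionGeneLinks",
           function(object) standardGeneric("reactionGeneLinks"))
#' @export
setMethod("reactionGeneLinks", "MetabolicNetwork",
          function(object) object@reactionGenes)

#' @describeIn MetabolicNetwork-class reaction-metabolite-role link table
#' @export
setGeneric("reactionMetaboliteLinks",
           function(object) standardGeneric("reactionMetaboliteLinks"))
#' @export
setMethod("reactionMetaboliteLinks", "MetabolicNetwork",
          function(object) object@reactionMetabolites)

#' @describeIn MetabolicNetwork-class declared compartment set
#' @export
setGeneric("compartments", function(object) standardGeneric("compartments"))
#' @export
setMethod("compartments", "MetabolicNetwork",
          function(object) sort(unique(object@metabolites$compartment)))

#' @describeIn GMCohort-class expression matrix accessor
#' @param object a `GMCohort`
#' @export
setGeneric("expressionMatrix",
           function(object) standardGeneric("expressionMatrix"))
#' @export
setMethod("expressionMatrix", "GMCohort", function(object) object@expression)

#' @describeIn GMCohort-class metabolite matrix accessor
#' @export
setGeneric("metaboliteMatrix",
           function(object) standardGeneric("metaboliteMatrix"))
#' @export
setMethod("metaboliteMatrix", "GMCohort", function(object) object@metabolites)

#' @describeIn GMCohort-class per-sample metadata accessor
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))
#' @export
setMethod("sampleData", "GMCohort", function(object) object@sampleData)

#' @describeIn GMCohort-class condition label per sample
#' @export
setGeneric("conditionLabels",
           function(object) standardGeneric("conditionLabels"))
#' @export
setMethod("conditionLabels", "GMCohort",
          function(object) object@sampleData$condition)

#' Select the sample indices of a stratum
#'
#' @param cohort a [GMCohort-class].
#' @param stratum `"all"`, `"noncancerous"` or `"cancer"`.
#' @return integer vector of sample indices.
#' @export
stratumSamples <- function(cohort,
                           stratum = c("all", "noncancerous", "cancer")) {
  stratum <- match.arg(stratum)
  if (stratum == "all") seq_len(nrow(sampleData(cohort)))
  else which(conditionLabels(cohort) == stratum)
}
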