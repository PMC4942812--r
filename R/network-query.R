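# Connected gene-metabolite pairs and RGM triplet enumeration.

#' Enumerate connected gene-metabolite pairs
#'
#' A gene and a metabolite are *connected* when the gene's enzyme product
#' catalyzes at least one reaction that consumes or produces the metabolite.
#' Each pair is returned once, with its full set of connecting reactions.
#'
#' @param network a [MetabolicNetwork-class].
#' @param compartment optional compartment filter (e.g. `"c"` to keep only
#'   cytoplasmic metabolites); `NULL` keeps all compartments.
#' @return data.frame with columns `gene_id`, `metabolite_id` and a
#'   list-column `reaction_ids` (sorted connecting reactions), ordered by
#'   gene then metabolite network index.
#' @export
connectedGMPairs <- function(network, compartment = NULL) {
  rg <- reactionGeneLinks(network)
  rm_ <- reactionMetaboliteLinks(network)
  if (!is.null(compartment)) {
    keep <- networkMetabolites(network)
    keep <- keep$metabolite_id[keep$compartment %in% compartment]
    rm_ <- rm_[rm_$metabolite_id %in% keep, , drop = FALSE]
  }
  if (nrow(rg) == 0L || nrow(rm_) == 0L)
    return(data.frame(gene_id = character(0), metabolite_id = character(0),
                      reaction_ids = I(list())))
  j <- merge(rg, unique(rm_[, c("reaction_id", "metabolite_id")]),
             by = "reaction_id")
  key <- paste(j$gene_id, j$metabolite_id, sep = "\r")
  rxSets <- split(j$reaction_id, key)
  ids <- do.call(rbind, strsplit(names(rxSets), "\r", fixed = TRUE))
  out <- data.frame(gene_id = ids[, 1L], metabolite_id = ids[, 2L],
                    stringsAsFactors = FALSE)
  out$reaction_ids <- I(lapply(rxSets, function(v) sort(unique(v))))
  gi <- networkGenes(network)
  mi <- networkMetabolites(network)
  ord <- order(gi$network_index[match(out$gene_id, gi$gene_id)],
               mi$network_index[match(out$metabolite_id, mi$metabolite_id)])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate reaction-gene-metabolite (RGM) triplets
#'
#' One triplet per (reaction, catalyzing gene, participating metabolite,
#' role). A metabolite acting as both substrate and product of the same
#' reaction (e.g. a transporter's two compartment faces collapsing to one
#' ID) yields two triplets, one per role, because the substrate/product flag
#' is a role-specific classifier feature.
#'
#' @param network a [MetabolicNetwork-class].
#' @param extendCompartments when `FALSE` (default) only cytoplasmic
#'   (`"c"`) metabolites are enumerated; when `TRUE`, metabolites of all
#'   compartments.
#' @return data.frame with columns `reaction_id`, `gene_id`,
#'   `metabolite_id`, `is_substrate` (logical), ordered deterministically by
#'   (reaction index, gene index, metabolite index, substrate before
#'   product).
#' @export
enumerateRGMTriplets <- function(network, extendCompartments = FALSE) {
  rg <- reactionGeneLinks(network)
  rm_ <- reactionMetaboliteLinks(network)
  if (!extendCompartments) {
    mets <- networkMetabolites(network)
    cyto <- mets$metabolite_id[mets$compartment == "c"]
    rm_ <- rm_[rm_$metabolite_id %in% cyto, , drop = FALSE]
  }
  j <- merge(rg, rm_, by = "reaction_id")
  out <- data.frame(reaction_id = j$reaction_id, gene_id = j$gene_id,
                    metabolite_id = j$metabolite_id,
                    is_substrate = j$role == "substrate",
                    stringsAsFactors = FALSE)
  rx <- reactions(network); gi <- networkGenes(network)
  mi <- networkMetabolites(network)
  ord <- order(rx$network_index[match(out$reaction_id, rx$reaction_id)],
               gi$network_index[match(out$gene_id, gi$gene_id)],
               mi$network_index[match(out$metabolite_id, mi$metabolite_id)],
               !out$is_substrate)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
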