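# Significant gene-metabolite bipartite graph, degree analysis and hub
# pathway enrichment.

#' Build the significant gene-metabolite bipartite graph
#'
#' One undirected edge per FDR-significant connected pair; all measured
#' genes and metabolites of the association table are retained as vertices,
#' so isolated nodes keep degree 0. Vertices carry a `kind` attribute
#' (`"gene"` / `"metabolite"`) and the igraph bipartite `type`.
#'
#' @param assocTable output of [spearmanTable()] for one stratum.
#' @param alpha FDR level, default 0.05.
#' @return an [igraph::igraph] with graph attribute `stratum`.
#' @export
buildGMGraph <- function(assocTable, alpha = 0.05) {
  stopifnot(length(unique(assocTable$stratum)) == 1L)
  genes <- unique(assocTable$gene_id)
  mets <- unique(assocTable$metabolite_id)
  sig <- assocTable[assocTable$q < alpha, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes, kind = "gene",
                            type = FALSE)
  g <- igraph::add_vertices(g, length(mets), name = mets,
                            kind = "metabolite", type = TRUE)
  if (nrow(sig) > 0L)
    g <- igraph::add_edges(g, rbind(match(sig$gene_id, c(genes, mets)),
                                    length(genes) +
                                      match(sig$metabolite_id, mets)))
  g <- igraph::set_graph_attr(g, "stratum", unique(assocTable$stratum))
  g
}

#' Node degrees and hub filter of a GM graph
#'
#' @param graph a graph from [buildGMGraph()].
#' @param minDegree hub cutoff: nodes with degree strictly greater than
#'   this are flagged (default 4).
#' @return data.frame with `node`, `kind`, `degree`, `hub`.
#' @export
degreeTable <- function(graph, minDegree = 4) {
  d <- igraph::degree(graph)
  data.frame(node = igraph::V(graph)$name,
             kind = igraph::V(graph)$kind,
             degree = as.integer(d),
             hub = d > minDegree,
             stringsAsFactors = FALSE)
}

#' Pathway enrichment of hub genes
#'
#' For each pathway, an upper-tail hypergeometric test of the overlap
#' between hub genes (degree > `degreeThreshold`) and the pathway's genes
#' (a gene belongs to every pathway of every reaction it catalyzes), within
#' the population of all gene vertices; BH-adjusted across pathways.
#'
#' @param graph a graph from [buildGMGraph()].
#' @param network the [MetabolicNetwork-class] supplying gene-pathway
#'   membership.
#' @param degreeThreshold hub cutoff (degree strictly greater), default 4.
#' @return data.frame with `pathway`, `pathway_id`, `nHub`, `nPathwayGenes`,
#'   `p`, `q`, ordered by `p`.
#' @export
hubPathwayEnrichment <- function(graph, network, degreeThreshold = 4) {
  dt <- degreeTable(graph, degreeThreshold)
  pop <- dt$node[dt$kind == "gene"]
  hubs <- dt$node[dt$kind == "gene" & dt$hub]
  rx <- reactions(network)
  rg <- reactionGeneLinks(network)
  gp <- unique(data.frame(
    gene_id = rg$gene_id,
    pathway = rx$pathway[match(rg$reaction_id, rx$reaction_id)],
    pathway_id = rx$pathway_id[match(rg$reaction_id, rx$reaction_id)],
    stringsAsFactors = FALSE))
  gp <- gp[gp$gene_id %in% pop, , drop = FALSE]
  paths <- unique(gp[, c("pathway", "pathway_id")])
  res <- lapply(seq_len(nrow(paths)), function(i) {
    inPath <- unique(gp$gene_id[gp$pathway_id == paths$pathway_id[i]])
    ov <- length(intersect(hubs, inPath))
    p <- if (length(hubs) == 0L) 1 else
      hypergeomUpperP(ov, length(hubs), length(pop), length(inPath))
    data.frame(pathway = paths$pathway[i], pathway_id = paths$pathway_id[i],
               nHub = ov, nPathwayGenes = length(inPath), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bhFDR(res$p)
  res[order(res$p), , drop = FALSE]
}

#' Export a GM graph to GraphML
#'
#' @param graph a graph from [buildGMGraph()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGMGraph <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
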