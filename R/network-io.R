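# Flat TSV network dialect: one reaction per row, list fields
# semicolon-delimited, metabolite tokens suffixed "[compartment]".
# Columns: reaction_id, genes, substrates, products, reversible {0,1},
# delta_g0, pathway.

splitList <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

metCompartment <- function(tok) {
  ifelse(grepl("\\[[^][]+\\]$", tok), sub(".*\\[([^][]+)\\]$", "\\1", tok), "c")
}

#' Read a metabolic network from TSV
#'
#' Parses the flat reaction-per-row dialect (list fields `;`-delimited,
#' metabolite tokens carrying a `[compartment]` suffix, `"c"` = cytoplasm)
#' into a validated [MetabolicNetwork-class]. `network_index` values are
#' assigned in lexicographic ID order per entity class; pathway labels are
#' encoded to integer codes by first appearance.
#'
#' @param path TSV file with columns `reaction_id`, `genes`, `substrates`,
#'   `products`, `reversible` (0/1), `delta_g0`, `pathway`.
#' @param declaredGenes,declaredMetabolites optional ID universes; when
#'   supplied, any reference outside them raises an error naming the
#'   offenders.
#' @return a [MetabolicNetwork-class].
#' @export
readNetwork <- function(path, declaredGenes = NULL,
                        declaredMetabolites = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  networkFromTable(tab, declaredGenes, declaredMetabolites)
}

# Build the network object from the parsed reaction table (shared by
# readNetwork and the synthetic generator, guaranteeing the round-trip).
networkFromTable <- function(tab, declaredGenes = NULL,
                             declaredMetabolites = NULL) {
  need <- c("reaction_id", "genes", "substrates", "products", "reversible",
            "delta_g0", "pathway")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("network table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$reaction_id))
    stop("duplicate reaction_id: ",
         paste(unique(tab$reaction_id[duplicated(tab$reaction_id)]),
               collapse = ", "))

  geneL <- splitList(tab$genes)
  subL  <- splitList(tab$substrates)
  prodL <- splitList(tab$products)

  allGenes <- sort(unique(unlist(geneL)))
  allMets  <- sort(unique(unlist(c(subL, prodL))))
  if (!is.null(declaredGenes)) {
    bad <- setdiff(allGenes, declaredGenes)
    if (length(bad))
      stop("network references undeclared gene(s): ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(declaredMetabolites)) {
    bad <- setdiff(allMets, declaredMetabolites)
    if (length(bad))
      stop("network references undeclared metabolite(s): ",
           paste(bad, collapse = ", "))
  }

  rxOrder <- order(tab$reaction_id)
  reactions <- data.frame(
    reaction_id   = tab$reaction_id,
    network_index = match(tab$reaction_id, sort(tab$reaction_id)),
    pathway       = tab$pathway,
    pathway_id    = match(tab$pathway, unique(tab$pathway)),
    delta_g0      = as.numeric(tab$delta_g0),
    reversible    = as.integer(tab$reversible) == 1L,
    stringsAsFactors = FALSE
  )
  genes <- data.frame(gene_id = allGenes,
                      network_index = seq_along(allGenes),
                      stringsAsFactors = FALSE)
  metabolites <- data.frame(metabolite_id = allMets,
                            compartment = metCompartment(allMets),
                            network_index = seq_along(allMets),
                            stringsAsFactors = FALSE)
  rg <- data.frame(
    reaction_id = rep(tab$reaction_id, lengths(geneL)),
    gene_id = unlist(geneL), stringsAsFactors = FALSE)
  rg <- unique(rg)
  rm_ <- rbind(
    data.frame(reaction_id = rep(tab$reaction_id, lengths(subL)),
               metabolite_id = unlist(subL), role = "substrate",
               stringsAsFactors = FALSE),
    data.frame(reaction_id = rep(tab$reaction_id, lengths(prodL)),
               metabolite_id = unlist(prodL), role = "product",
               stringsAsFactors = FALSE))
  rm_ <- unique(rm_)

  net <- new("MetabolicNetwork", reactions = reactions, genes = genes,
             metabolites = metabolites, reactionGenes = rg,
             reactionMetabolites = rm_)
  validObject(net)
  net
}

#' Write a metabolic network to TSV
#'
#' Inverse of [readNetwork()]: emits the flat reaction-per-row dialect with
#' deterministic (sorted) list fields, so write -> read round-trips to an
#' identical structure.
#'
#' @param network a [MetabolicNetwork-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(network, path) {
  rx <- reactions(network)
  rg <- reactionGeneLinks(network)
  rm_ <- reactionMetaboliteLinks(network)
  collapse <- function(ids) paste(sort(ids), collapse = ";")
  rows <- data.frame(
    reaction_id = rx$reaction_id,
    genes = vapply(rx$reaction_id, function(r)
      collapse(rg$gene_id[rg$reaction_id == r]), ""),
    substrates = vapply(rx$reaction_id, function(r)
      collapse(rm_$metabolite_id[rm_$reaction_id == r &
                                 rm_$role == "substrate"]), ""),
    products = vapply(rx$reaction_id, function(r)
      collapse(rm_$metabolite_id[rm_$reaction_id == r &
                                 rm_$role == "product"]), ""),
    reversible = as.integer(rx$reversible),
    delta_g0 = rx$delta_g0,
    pathway = rx$pathway,
    stringsAsFactors = FALSE
  )
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map measured omics identifiers onto the network
#'
#' Metabolites are mapped first by their HMDB key and, only where the HMDB
#' key is absent or unmatched, by their KEGG key; genes are mapped by their
#' Entrez key. A measured ID whose key matches more than one network entity
#' raises an ambiguity error rather than choosing silently.
#'
#' @param network a [MetabolicNetwork-class].
#' @param measuredGeneIds,measuredMetaboliteIds character vectors of measured
#'   IDs.
#' @param idMaps data.frame with columns `measured_id`, `key_type`
#'   (`"HMDB"`, `"KEGG"` or `"ENTREZ"`), `network_id`.
#' @return list with `geneMap` / `metaboliteMap` data.frames
#'   (`measured_id`, `network_id`, and `key` used for metabolites) and
#'   `unmappedGenes` / `unmappedMetabolites` character vectors.
#' @export
mapOmicsIds <- function(network, measuredGeneIds, measuredMetaboliteIds,
                        idMaps) {
  stopifnot(all(c("measured_id", "key_type", "network_id") %in%
                names(idMaps)))
  netMets <- networkMetabolites(network)$metabolite_id
  netGenes <- networkGenes(network)$gene_id

  lookup <- function(id, keyType, universe) {
    hit <- idMaps$network_id[idMaps$measured_id == id &
                             idMaps$key_type == keyType]
    hit <- unique(hit[hit %in% universe])
    if (length(hit) > 1L)
      stop(sprintf("ambiguous %s mapping for '%s': matches %s",
                   keyType, id, paste(hit, collapse = ", ")))
    if (length(hit) == 1L) hit else NA_character_
  }

  metRows <- lapply(measuredMetaboliteIds, function(id) {
    hit <- lookup(id, "HMDB", netMets)
    key <- "HMDB"
    if (is.na(hit)) { hit <- lookup(id, "KEGG", netMets); key <- "KEGG" }
    data.frame(measured_id = id, network_id = hit,
               key = if (is.na(hit)) NA_character_ else key,
               stringsAsFactors = FALSE)
  })
  metMap <- do.call(rbind, metRows)
  dupNet <- metMap$network_id[!is.na(metMap$network_id)]
  if (anyDuplicated(dupNet))
    stop("multiple measured metabolites map to network metabolite(s): ",
         paste(unique(dupNet[duplicated(dupNet)]), collapse = ", "))

  geneRows <- lapply(measuredGeneIds, function(id) {
    data.frame(measured_id = id, network_id = lookup(id, "ENTREZ", netGenes),
               stringsAsFactors = FALSE)
  })
  geneMap <- do.call(rbind, geneRows)

  list(
    geneMap = geneMap[!is.na(geneMap$network_id), , drop = FALSE],
    metaboliteMap = metMap[!is.na(metMap$network_id), , drop = FALSE],
    unmappedGenes = geneMap$measured_id[is.na(geneMap$network_id)],
    unmappedMetabolites = metMap$measured_id[is.na(metMap$network_id)]
  )
}
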