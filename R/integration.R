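#' Canonicalize a free-text pathway name
#'
#' Case-folds, unifies "/" with " or ", strips punctuation other than hyphens
#' (so stereo-prefixes like "d-" survive) and collapses whitespace, so the
#' spelling variants that occur across annotation sources (e.g.
#' "Glycolysis/gluconeogenesis" vs "glycolysis or gluconeogenesis") map to the
#' same key. Idempotent.
#'
#' @param x character vector of pathway names.
#' @return character vector of canonical keys.
#' @export
canonicalizeName <- function(x) {
  out <- tolower(x)
  out <- gsub("\\s*/\\s*", " or ", out)
  out <- gsub("[^a-z0-9 -]", " ", out)
  out <- gsub("\\s+-\\s+", " ", out)       # free-standing dashes
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

#' Intersect the metabonomics and systems-pharmacology pathway sets
#'
#' Partitions the metabonomics pathway set by canonical-name membership in the
#' systems-pharmacology set; both parts keep their original display names.
#'
#' @param metab_names significant pathway names from the metabonomics arm.
#' @param syspharm_names pathway names from the systems-pharmacology arm.
#' @return list with `overlapping` and `non_overlapping` character vectors.
#' @export
overlapPathways <- function(metab_names, syspharm_names) {
  keys <- canonicalizeName(syspharm_names)
  inset <- canonicalizeName(metab_names) %in% keys
  list(overlapping = metab_names[inset], non_overlapping = metab_names[!inset])
}

#' Reverse-map overlapping pathways to proteins, compounds and herbs
#'
#' Keeps exactly the proteins annotated to at least one overlapping pathway,
#' the compounds hitting at least one kept protein, and the herbs containing
#' at least one kept compound, then assembles the typed herb-compound-
#' protein-pathway network with degrees computed on the induced subgraph.
#'
#' @param overlap_names names of the overlapping pathways.
#' @param protein_pathway data.frame with columns `protein`, `pathway`
#'   (pathway display names).
#' @param compound_protein data.frame with columns `compound`, `protein`.
#' @param herb_compound data.frame with columns `herb`, `compound`.
#' @return a [CompoundTargetNetwork-class]; empty (with a warning) when the
#'   overlap is empty.
#' @export
reverseMap <- function(overlap_names, protein_pathway, compound_protein,
                       herb_compound) {
  keys <- canonicalizeName(overlap_names)
  pp <- protein_pathway[canonicalizeName(protein_pathway$pathway) %in% keys, ,
                        drop = FALSE]
  if (nrow(pp) == 0) {
    warning("empty pathway overlap: returning an empty network")
    g <- igraph::make_empty_graph(directed = FALSE)
    return(new("CompoundTargetNetwork", graph = g,
               tiers = c(herb = 0L, compound = 0L, protein = 0L, pathway = 0L)))
  }
  prot_keep <- unique(pp$protein)
  cp <- compound_protein[compound_protein$protein %in% prot_keep, , drop = FALSE]
  comp_keep <- unique(cp$compound)
  hc <- herb_compound[herb_compound$compound %in% comp_keep, , drop = FALSE]
  herb_keep <- unique(hc$herb)
  path_keep <- unique(pp$pathway)

  vname <- c(
    paste0("herb:", herb_keep), paste0("compound:", comp_keep),
    paste0("protein:", prot_keep), paste0("pathway:", path_keep)
  )
  vtier <- c(
    rep("herb", length(herb_keep)), rep("compound", length(comp_keep)),
    rep("protein", length(prot_keep)), rep("pathway", length(path_keep))
  )
  vlabel <- c(herb_keep, comp_keep, prot_keep, path_keep)
  edges <- rbind(
    if (nrow(hc)) cbind(paste0("herb:", hc$herb), paste0("compound:", hc$compound),
                        "contains"),
    if (nrow(cp)) cbind(paste0("compound:", cp$compound), paste0("protein:", cp$protein),
                        "targets"),
    if (nrow(pp)) cbind(paste0("protein:", pp$protein), paste0("pathway:", pp$pathway),
                        "participates")
  )
  edges <- unique(edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], relation = edges[, 3],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = vname, tier = vtier, label = vlabel,
                          stringsAsFactors = FALSE)
  )
  igraph::V(g)$degree <- igraph::degree(g)
  new("CompoundTargetNetwork", graph = g, tiers = c(
    herb = length(herb_keep), compound = length(comp_keep),
    protein = length(prot_keep), pathway = length(path_keep)
  ))
}

#' Export a layered network to Cytoscape-consumable files
#'
#' Writes SIF (one typed interaction per line) and/or GraphML with tier and
#' degree vertex attributes.
#'
#' @param network a [CompoundTargetNetwork-class].
#' @param path output path without extension.
#' @param formats subset of `c("sif", "graphml")`.
#' @return invisibly, the files written.
#' @export
exportNetwork <- function(network, path, formats = c("sif", "graphml")) {
  if (igraph::vcount(network@graph) == 0) stop("network is empty")
  writeNetworkFiles(network@graph, path, formats = formats)
}

#' Read back a GraphML network export
#'
#' @param path a `.graphml` file written by [exportNetwork()].
#' @return a [CompoundTargetNetwork-class].
#' @export
readNetworkGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  tier <- igraph::V(g)$tier
  tiers <- vapply(c("herb", "compound", "protein", "pathway"),
                  function(t) sum(tier == t), integer(1))
  new("CompoundTargetNetwork", graph = g, tiers = tiers)
}
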