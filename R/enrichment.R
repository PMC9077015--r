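#' Construct a pathway library
#'
#' @param pathways data.frame with columns `pathway_id`, `name`.
#' @param compounds named list (by pathway id) of compound member ids.
#' @param proteins named list of protein member ids (may be empty lists).
#' @param edges named list of two-column compound edge matrices (optional).
#' @param provenance free-text source tag.
#' @return a [PathwayLibrary-class].
#' @export
pathwayLibrary <- function(pathways, compounds, proteins = NULL, edges = NULL,
                           provenance = "user") {
  ids <- pathways$pathway_id
  if (is.null(proteins)) proteins <- setNames(rep(list(character(0)), length(ids)), ids)
  if (is.null(edges)) edges <- setNames(rep(list(NULL), length(ids)), ids)
  new("PathwayLibrary", pathways = pathways, compounds = compounds,
      proteins = proteins, edges = edges, provenance = provenance)
}

#' Match query metabolites to pathway compound members
#'
#' Identifier-based matching: KEGG compound ids are matched first; query names
#' are used as a case-insensitive fallback against member ids. Lipid-class
#' entries are expected to have been excluded upstream.
#'
#' @param query data.frame with columns `query` and `kegg` (id may be NA), or
#'   a character vector of ids.
#' @param library a [PathwayLibrary-class].
#' @return named list (by pathway id) of matched member ids; unmatched query
#'   entries in `attr(, "unmatched")`.
#' @export
matchMetabolites <- function(query, library) {
  stopifnot(is(library, "PathwayLibrary"))
  if (is.character(query)) query <- data.frame(query = query, kegg = query,
                                               stringsAsFactors = FALSE)
  ids <- ifelse(is.na(query$kegg), query$query, query$kegg)
  hit_any <- rep(FALSE, length(ids))
  hits <- lapply(pathwayIds(library), function(pid) {
    members <- library@compounds[[pid]]
    h <- members[tolower(members) %in% tolower(ids)]
    hit_any <<- hit_any | tolower(ids) %in% tolower(members)
    h
  })
  names(hits) <- pathwayIds(library)
  attr(hits, "unmatched") <- query$query[!hit_any]
  hits
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' P(X >= hits) when drawing `query_size` compounds from a universe of
#' `universe` compounds of which `total` belong to the pathway.
#'
#' @param hits matched compounds in the pathway.
#' @param total pathway size.
#' @param query_size number of query compounds present in the universe.
#' @param universe reference-set size.
#' @return the raw p-value.
#' @export
oraPvalue <- function(hits, total, query_size, universe) {
  if (hits > min(total, query_size) || total > universe || query_size > universe ||
      any(c(hits, total, query_size, universe) < 0))
    stop("inconsistent counts for the hypergeometric test")
  phyper(hits - 1, total, universe - total, query_size, lower.tail = FALSE)
}

#' Natural-log significance transform
#'
#' @param p probability in (0, 1].
#' @return -ln(p).
#' @export
negLogP <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  -log(p)
}

#' Topology impact of matched compounds in a pathway graph
#'
#' Node importance is betweenness centrality on the undirected simple
#' compound graph, normalized so importances over the pathway sum to one;
#' the impact is the summed importance of the matched nodes. When every
#' centrality is zero (e.g. a 2-node pathway) the impact is zero.
#'
#' @param hit_ids matched compound ids.
#' @param members all compound members of the pathway.
#' @param edges two-column matrix/data.frame of edges on the members (may be
#'   NULL or empty).
#' @return impact in `[0, 1]`.
#' @export
pathwayImpact <- function(hit_ids, members, edges = NULL) {
  if (length(hit_ids) && !all(hit_ids %in% members))
    stop("hit node(s) absent from the pathway graph: ",
         paste(setdiff(hit_ids, members), collapse = ", "))
  if (length(hit_ids) == 0) return(0)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(members), name = members)
  if (!is.null(edges) && length(edges) && nrow(as.matrix(edges)) > 0) {
    em <- as.matrix(edges)
    g <- igraph::add_edges(g, rbind(em[, 1], em[, 2]))
    g <- igraph::simplify(g)
  }
  btw <- igraph::betweenness(g, directed = FALSE)
  tot <- sum(btw)
  if (tot == 0) return(0)
  importance <- btw / tot
  sum(importance[hit_ids])
}

#' Build the ranked pathway over-representation table
#'
#' One row per pathway with at least one matched compound: hit count, pathway
#' size, raw hypergeometric p, -ln(p), topology impact, and the selection
#' flags (`significant` at p < `p_cut`, `high_impact` at impact >
#' `impact_cut`). Rows are sorted by p ascending with ties broken by pathway
#' name.
#'
#' @param query data.frame with `query` and `kegg` columns (see
#'   [matchMetabolites()]).
#' @param library a [PathwayLibrary-class].
#' @param universe reference-set size; defaults to the number of distinct
#'   compounds in the library.
#' @param p_cut significance cutoff on the raw p (default 0.05).
#' @param impact_cut impact cutoff (default 0.1).
#' @return data.frame with columns `pathway_id`, `name`, `hits`, `total`,
#'   `raw_p`, `neg_log_p`, `impact`, `significant`, `high_impact`.
#' @export
buildEnrichmentTable <- function(query, library, universe = NULL,
                                 p_cut = 0.05, impact_cut = 0.1) {
  if (is.null(universe))
    universe <- length(unique(unlist(library@compounds)))
  hitsets <- matchMetabolites(query, library)
  ids_in_universe <- unique(unlist(library@compounds))
  if (is.character(query)) query <- data.frame(query = query, kegg = query,
                                               stringsAsFactors = FALSE)
  qids <- ifelse(is.na(query$kegg), query$query, query$kegg)
  qsize <- sum(tolower(qids) %in% tolower(ids_in_universe))
  nm <- pathwayNames(library)
  rows <- list()
  for (pid in pathwayIds(library)) {
    h <- hitsets[[pid]]
    if (length(h) == 0) next
    total <- length(library@compounds[[pid]])
    p <- oraPvalue(length(h), total, qsize, universe)
    imp <- pathwayImpact(h, library@compounds[[pid]], library@edges[[pid]])
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_id = pid, name = unname(nm[pid]), hits = length(h),
      total = total, raw_p = p, neg_log_p = negLogP(p), impact = imp,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    pathway_id = character(0), name = character(0), hits = integer(0),
    total = integer(0), raw_p = numeric(0), neg_log_p = numeric(0),
    impact = numeric(0), stringsAsFactors = FALSE
  )
  out <- out[order(out$raw_p, out$name), , drop = FALSE]
  out$significant <- out$raw_p < p_cut
  out$high_impact <- out$impact > impact_cut
  rownames(out) <- NULL
  out
}

#' Read/write a pathway library in GMT-like text form
#'
#' Each pathway is three tab-separated lines: `id<TAB>name<TAB>compound ids`,
#' `.proteins<TAB>protein ids` and `.edges<TAB>from|to pairs` (the latter two
#' may list nothing).
#'
#' @param library a [PathwayLibrary-class].
#' @param path file path.
#' @return `writePathwayLibrary` the path invisibly; `readPathwayLibrary` a
#'   [PathwayLibrary-class].
#' @export
writePathwayLibrary <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pid in pathwayIds(library)) {
    nm <- unname(pathwayNames(library)[pid])
    writeLines(paste(c(pid, nm, library@compounds[[pid]]), collapse = "\t"), con)
    writeLines(paste(c(".proteins", library@proteins[[pid]]), collapse = "\t"), con)
    e <- library@edges[[pid]]
    epairs <- if (!is.null(e) && nrow(as.matrix(e)))
      apply(as.matrix(e), 1, paste, collapse = "|") else character(0)
    writeLines(paste(c(".edges", epairs), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname writePathwayLibrary
#' @param provenance source tag for the loaded library.
#' @export
readPathwayLibrary <- function(path, provenance = basename(path)) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 3 == 0)
  ids <- character(); nms <- character()
  compounds <- list(); proteins <- list(); edges <- list()
  for (i in seq(1, length(lines), by = 3)) {
    f1 <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f2 <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    f3 <- strsplit(lines[i + 2], "\t", fixed = TRUE)[[1]]
    pid <- f1[1]
    ids <- c(ids, pid); nms <- c(nms, f1[2])
    compounds[[pid]] <- f1[-(1:2)]
    proteins[[pid]] <- f2[-1]
    ep <- f3[-1]
    edges[[pid]] <- if (length(ep))
      do.call(rbind, strsplit(ep, "|", fixed = TRUE)) else NULL
  }
  pathwayLibrary(
    data.frame(pathway_id = ids, name = nms, stringsAsFactors = FALSE),
    compounds, proteins, edges, provenance = provenance
  )
}
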