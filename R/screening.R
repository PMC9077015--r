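#' ADME screening criteria
#'
#' The four-descriptor screen for active herbal compounds: oral bioavailability
#' OB >= 30 percent, blood-brain-barrier index BBB > 0.3 (strict), drug-likeness
#' DL >= 0.18 and half-life HL >= 4 h. Comparisons are exact floating-point
#' comparisons; only the BBB bound is strict, mirroring how the thresholds are
#' conventionally stated.
#'
#' @param ob_min minimum oral bioavailability in percent (inclusive).
#' @param bbb_min minimum blood-brain-barrier index (exclusive).
#' @param dl_min minimum drug-likeness (inclusive).
#' @param hl_min minimum half-life in hours (inclusive).
#' @return an object of class `ScreenCriteria` (a named list).
#' @export
screenCriteria <- function(ob_min = 30, bbb_min = 0.3, dl_min = 0.18, hl_min = 4) {
  structure(
    list(ob_min = ob_min, bbb_min = bbb_min, dl_min = dl_min, hl_min = hl_min),
    class = "ScreenCriteria"
  )
}

#' Literature whitelist for the screen
#'
#' Entries are (compound name, herb code, citation note); a whitelisted
#' compound present in the input is retained regardless of its property
#' values. `defaultWhitelist()` ships the case-study entries: taurine and
#' betaine for Chinese angelica (DG) and the six cinnamon-bark (RG) volatiles
#' retained despite low drug-likeness.
#'
#' @param name,herb,note equal-length character vectors.
#' @return data.frame with columns `name`, `herb`, `note`.
#' @export
whitelist <- function(name = character(), herb = character(), note = character()) {
  stopifnot(length(name) == length(herb))
  if (length(note) == 0) note <- rep("", length(name))
  data.frame(name = name, herb = herb, note = note, stringsAsFactors = FALSE)
}

#' @rdname whitelist
#' @export
defaultWhitelist <- function() {
  whitelist(
    name = c(
      "taurine", "betaine",
      "cinnamaldehyde", "styrone", "(l)-alpha-terpineol",
      "(-)-caryophyllene oxide", "(Z)-caryophyllene", "[(1S)-endo]-(-)-borneol"
    ),
    herb = c("DG", "DG", rep("RG", 6)),
    note = c(
      rep("reported pharmacological component of DG", 2),
      rep("volatile-oil constituent of RG retained despite low DL", 6)
    )
  )
}

#' Screen herb compounds by the four ADME criteria
#'
#' Retains every record passing all four threshold comparisons, plus every
#' whitelisted (name, herb) pair present in the input. Records with a missing
#' property value are rejected (not an error) with the reason recorded.
#' Duplicate compound ids across herbs are merged into one record carrying the
#' herb set.
#'
#' @param records data.frame with columns `compound_id`, `name`, `herb`
#'   (one row per compound-herb pair; repeated ids are merged), `OB`, `BBB`,
#'   `DL`, `HL`.
#' @param criteria a [screenCriteria()] object.
#' @param wl a [whitelist()] data.frame (may be empty).
#' @return data.frame of retained records with `herbs` (comma-separated herb
#'   codes) and `pass_reason` (`"screen"` or `"whitelist"`); rejected records
#'   with their reasons are attached as `attr(, "rejected")`.
#' @export
screenCompounds <- function(records, criteria = screenCriteria(),
                            wl = whitelist()) {
  need <- c("compound_id", "name", "herb", "OB", "BBB", "DL", "HL")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (nrow(records) == 0) {
    out <- records[, c("compound_id", "name")]
    out$herbs <- character(0)
    out$OB <- out$BBB <- out$DL <- out$HL <- numeric(0)
    out$pass_reason <- character(0)
    attr(out, "rejected") <- data.frame(compound_id = character(0),
                                        reason = character(0))
    return(out)
  }

  # merge duplicate compound ids into one record with a herb set
  merged <- do.call(rbind, lapply(split(records, records$compound_id), function(d) {
    data.frame(
      compound_id = d$compound_id[1], name = d$name[1],
      herbs = paste(sort(unique(d$herb)), collapse = ","),
      OB = d$OB[1], BBB = d$BBB[1], DL = d$DL[1], HL = d$HL[1],
      stringsAsFactors = FALSE
    )
  }))
  rownames(merged) <- NULL

  wl_key <- paste(tolower(wl$name), wl$herb, sep = "\r")
  reasons <- character(nrow(merged))
  keep <- logical(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    r <- merged[i, ]
    herbs_i <- strsplit(r$herbs, ",", fixed = TRUE)[[1]]
    in_wl <- any(paste(tolower(r$name), herbs_i, sep = "\r") %in% wl_key)
    vals <- c(OB = r$OB, BBB = r$BBB, DL = r$DL, HL = r$HL)
    if (anyNA(vals)) {
      if (in_wl) { keep[i] <- TRUE; reasons[i] <- "whitelist" }
      else reasons[i] <- paste0("missing ", paste(names(vals)[is.na(vals)], collapse = ","))
      next
    }
    pass <- r$OB >= criteria$ob_min && r$BBB > criteria$bbb_min &&
      r$DL >= criteria$dl_min && r$HL >= criteria$hl_min
    if (pass) { keep[i] <- TRUE; reasons[i] <- "screen" }
    else if (in_wl) { keep[i] <- TRUE; reasons[i] <- "whitelist" }
    else {
      fails <- c(
        if (r$OB < criteria$ob_min) "OB",
        if (r$BBB <= criteria$bbb_min) "BBB",
        if (r$DL < criteria$dl_min) "DL",
        if (r$HL < criteria$hl_min) "HL"
      )
      reasons[i] <- paste0("fails ", paste(fails, collapse = ","))
    }
  }
  out <- merged[keep, , drop = FALSE]
  out$pass_reason <- reasons[keep]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(
    compound_id = merged$compound_id[!keep],
    reason = reasons[!keep], stringsAsFactors = FALSE
  )
  out
}

#' Build the bipartite herb-active compound network
#'
#' Nodes are herbs and retained compounds; an edge joins a herb to each
#' compound retained for it. A compound shared by several herbs is a single
#' node whose degree is its herb count. An empty active set yields an empty
#' graph.
#'
#' @param active data.frame as returned by [screenCompounds()].
#' @return igraph object with vertex attribute `type` (`"herb"`/`"compound"`);
#'   per-herb retained-compound counts in `attr(, "herb_counts")`.
#' @export
buildHerbCompoundNetwork <- function(active) {
  if (nrow(active) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    attr(g, "herb_counts") <- integer(0)
    return(g)
  }
  pairs <- do.call(rbind, lapply(seq_len(nrow(active)), function(i) {
    herbs <- strsplit(active$herbs[i], ",", fixed = TRUE)[[1]]
    data.frame(herb = herbs, compound = active$compound_id[i],
               stringsAsFactors = FALSE)
  }))
  herbs <- sort(unique(pairs$herb))
  comps <- unique(pairs$compound)
  g <- igraph::graph_from_data_frame(
    pairs,
    directed = FALSE,
    vertices = data.frame(
      name = c(herbs, comps),
      type = c(rep("herb", length(herbs)), rep("compound", length(comps)))
    )
  )
  counts <- table(pairs$herb)
  attr(g, "herb_counts") <- setNames(as.integer(counts), names(counts))
  g
}

#' Per-herb retained compound counts
#'
#' @param network graph from [buildHerbCompoundNetwork()].
#' @return named integer vector.
#' @export
herbCompoundCounts <- function(network) attr(network, "herb_counts")

#' Write a network in SIF and/or GraphML form
#'
#' @param graph an igraph object.
#' @param path output path without extension.
#' @param relation interaction label used in the SIF lines.
#' @param formats subset of `c("sif", "graphml")`.
#' @return invisibly, the files written.
#' @export
writeNetworkFiles <- function(graph, path, relation = "contains",
                              formats = c("sif", "graphml")) {
  bad <- setdiff(formats, c("sif", "graphml"))
  if (length(bad))
    stop("unsupported format(s): ", paste(bad, collapse = ", "),
         "; supported: sif, graphml")
  files <- character()
  if ("sif" %in% formats) {
    el <- igraph::as_edgelist(graph)
    rel <- if (igraph::ecount(graph) > 0 &&
               !is.null(igraph::edge_attr(graph, "relation")))
      igraph::edge_attr(graph, "relation") else rep(relation, nrow(el))
    f <- paste0(path, ".sif")
    writeLines(paste(el[, 1], rel, el[, 2], sep = "\t"), f)
    files <- c(files, f)
  }
  if ("graphml" %in% formats) {
    f <- paste0(path, ".graphml")
    igraph::write_graph(graph, f, format = "graphml")
    files <- c(files, f)
  }
  invisible(files)
}
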