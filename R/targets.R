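#' Filter predicted targets by rank and Z-score
#'
#' Per compound, keeps pharmacophore-match hits with `fit_rank <= top_n` and
#' `z_score >= z_min` (both inclusive). The rank cutoff is applied within each
#' compound's own ranked list, reflecting per-compound query submission.
#'
#' @param hits data.frame with columns `compound_id`, `protein_id`,
#'   `fit_rank`, `z_score`.
#' @param top_n rank cutoff (default 300).
#' @param z_min Z-score cutoff (default 0.8).
#' @return list with `hits` (the filtered table, input order preserved) and
#'   `proteins` (data.frame `protein_id`, `n_compounds` of distinct supporting
#'   compounds, sorted by protein id).
#' @export
filterTargets <- function(hits, top_n = 300, z_min = 0.8) {
  need <- c("compound_id", "protein_id", "fit_rank", "z_score")
  if (!all(need %in% names(hits)))
    stop("hits must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(hits[, c("compound_id", "fit_rank")]))
    stop("duplicate (compound_id, fit_rank) pairs in hits")
  keep <- hits$fit_rank <= top_n & hits$z_score >= z_min
  kept <- hits[keep, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept)) {
    supp <- tapply(kept$compound_id, kept$protein_id,
                   function(x) length(unique(x)))
    proteins <- data.frame(
      protein_id = names(supp), n_compounds = as.integer(supp),
      stringsAsFactors = FALSE
    )
    proteins <- proteins[order(proteins$protein_id), , drop = FALSE]
    rownames(proteins) <- NULL
  } else {
    proteins <- data.frame(protein_id = character(0), n_compounds = integer(0))
  }
  list(hits = kept, proteins = proteins)
}

#' Annotate target proteins to pathways
#'
#' Returns the union of (a) library pathways whose protein members intersect
#' the input protein set (origin `"annotation"`) and (b) a literature-mined
#' list of extra pathway names (origin `"literature"`), canonicalized
#' identically to library names. A pathway found both ways is merged with
#' origin `"annotation;literature"`.
#'
#' @param protein_ids character vector of target protein identifiers.
#' @param library a [PathwayLibrary-class].
#' @param extra_pathways character vector of literature pathway names.
#' @return data.frame with columns `pathway_id` (NA for literature-only
#'   entries), `name`, `origin`, `n_supporting_proteins`; unmatched proteins in
#'   `attr(, "unmatched_proteins")`.
#' @export
annotatePathways <- function(protein_ids, library, extra_pathways = character()) {
  stopifnot(is(library, "PathwayLibrary"))
  protein_ids <- unique(protein_ids)
  ids <- pathwayIds(library)
  nm <- pathwayNames(library)
  rows <- list()
  matched <- character()
  for (id in ids) {
    inter <- intersect(library@proteins[[id]], protein_ids)
    if (length(inter)) {
      matched <- union(matched, inter)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = id, name = unname(nm[id]), origin = "annotation",
        n_supporting_proteins = length(inter), stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway_id = character(0), name = character(0),
               origin = character(0), n_supporting_proteins = integer(0),
               stringsAsFactors = FALSE)
  keys <- canonicalizeName(out$name)
  for (p in unique(extra_pathways)) {
    k <- canonicalizeName(p)
    j <- match(k, keys)
    if (!is.na(j)) {
      out$origin[j] <- "annotation;literature"
    } else {
      out <- rbind(out, data.frame(
        pathway_id = NA_character_, name = p, origin = "literature",
        n_supporting_proteins = 0L, stringsAsFactors = FALSE
      ))
      keys <- c(keys, k)
    }
  }
  rownames(out) <- NULL
  attr(out, "unmatched_proteins") <- setdiff(protein_ids, matched)
  out
}
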