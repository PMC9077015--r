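#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats approx cor cov prcomp qt phyper aov lm pf pt sd rnorm runif
#'   setNames var quantile
#' @importFrom utils read.delim write.table head
NULL

#' A single 1D NMR spectrum
#'
#' Holds one serum spectrum as a chemical-shift axis (ppm, stored descending as
#' acquired) and an intensity series, plus the sample identifier and group
#' label used downstream.
#'
#' @slot ppm numeric, strictly monotone chemical-shift axis in ppm.
#' @slot intensity numeric, same length as `ppm`, finite.
#' @slot sampleId character(1).
#' @slot group character(1) group label (e.g. control / model / treated).
#' @export
setClass("NMRSpectrum",
  representation(
    ppm = "numeric",
    intensity = "numeric",
    sampleId = "character",
    group = "character"
  )
)

setValidity("NMRSpectrum", function(object) {
  msg <- character()
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have equal length")
  if (length(object@ppm) >= 2) {
    d <- diff(object@ppm)
    if (!(all(d > 0) || all(d < 0)))
      msg <- c(msg, "ppm axis must be strictly monotone")
  }
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' A labelled collection of spectra
#'
#' @slot spectra list of [NMRSpectrum-class] objects.
#' @slot manifest data.frame with columns `sample_id`, `group`.
#' @export
setClass("SpectrumSet",
  representation(spectra = "list", manifest = "data.frame")
)

setValidity("SpectrumSet", function(object) {
  msg <- character()
  if (!all(vapply(object@spectra, is, logical(1), "NMRSpectrum")))
    msg <- c(msg, "all elements of spectra must be NMRSpectrum objects")
  ids <- vapply(object@spectra, function(s) s@sampleId, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "sample ids must be unique")
  if (!all(c("sample_id", "group") %in% names(object@manifest)))
    msg <- c(msg, "manifest needs sample_id and group columns")
  else if (!setequal(ids, object@manifest$sample_id))
    msg <- c(msg, "manifest sample ids must match the spectra")
  if (length(msg)) msg else TRUE
})

#' Bucketing specification
#'
#' Defaults follow standard serum practice: 0.004-ppm buckets over
#' delta 0.5-8.5 with the residual-water window delta 4.7-5.2 discarded and the
#' axis referenced to the lactate doublet at delta 1.33.
#'
#' @slot width numeric(1), bucket width in ppm (> 0).
#' @slot region numeric(2), `c(low, high)` integration region in ppm.
#' @slot exclusions list of numeric(2) windows dropped from the region.
#' @slot referencePattern character(1), name of the calibration pattern.
#' @slot referencePPM numeric(1), target shift of the reference pattern.
#' @export
setClass("BucketSpec",
  representation(
    width = "numeric",
    region = "numeric",
    exclusions = "list",
    referencePattern = "character",
    referencePPM = "numeric"
  ),
  prototype(
    width = 0.004,
    region = c(0.5, 8.5),
    exclusions = list(c(4.7, 5.2)),
    referencePattern = "lactate doublet",
    referencePPM = 1.33
  )
)

setValidity("BucketSpec", function(object) {
  msg <- character()
  if (length(object@width) != 1L || object@width <= 0)
    msg <- c(msg, "width must be a single positive number")
  if (length(object@region) != 2L || diff(object@region) <= 0)
    msg <- c(msg, "region must be c(low, high) with low < high")
  for (ex in object@exclusions) {
    if (length(ex) != 2L || diff(ex) <= 0)
      msg <- c(msg, "each exclusion must be c(low, high) with low < high")
    else if (ex[1] < object@region[1] || ex[2] > object@region[2])
      msg <- c(msg, "exclusions must lie inside the region")
  }
  if (length(msg)) msg else TRUE
})

#' Normalized bucket matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose assay holds total-sum
#' normalized bucket integrals: rows are buckets (bucket-center ppm in
#' `rowData`), columns are samples (group labels in `colData`). Raw row totals
#' are kept in `metadata(x)$totals` for audit.
#'
#' @export
setClass("NMRBucketMatrix", contains = "SummarizedExperiment")

setValidity("NMRBucketMatrix", function(object) {
  msg <- character()
  if (!"ppm" %in% names(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must carry bucket-center ppm")
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry group labels")
  a <- SummarizedExperiment::assay(object)
  if (ncol(a) > 0) {
    s <- colSums(a)
    if (any(abs(s - 1) > 1e-8))
      msg <- c(msg, "normalized sample profiles must each sum to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Latent-variable models
#'
#' `PCAModel` and `OPLSDAModel` share per-sample scores, per-variable loadings
#' and explained-variance bookkeeping. `OPLSDAModel` adds the orthogonal
#' component structure and the class-projection rule.
#'
#' @slot scores matrix of component scores (samples x components).
#' @slot loadings matrix of loadings (variables x components).
#' @slot R2X numeric, explained X-variance fraction per component.
#' @slot center numeric, column means used for scaling.
#' @slot scale numeric, column weights used for scaling.
#' @slot varnames character, variable (bucket) names.
#' @export
setClass("MultivariateModel",
  representation(
    scores = "matrix",
    loadings = "matrix",
    R2X = "numeric",
    center = "numeric",
    scale = "numeric",
    varnames = "character",
    "VIRTUAL"
  )
)

#' @rdname MultivariateModel-class
#' @export
setClass("PCAModel", contains = "MultivariateModel")

#' @rdname MultivariateModel-class
#' @slot scoresOrth matrix of orthogonal scores (samples x nOrth).
#' @slot weights numeric, predictive weight vector w.
#' @slot weightsOrth matrix of orthogonal weights.
#' @slot loadingsOrth matrix of orthogonal loadings.
#' @slot coef numeric(1), regression of centered y on the predictive score.
#' @slot yMean numeric(1), mean of the 0/1 class coding.
#' @slot y numeric, the centered class vector used in fitting.
#' @slot classes character(2), level names coded 0 and 1.
#' @slot R2Y numeric(1), explained class variance.
#' @slot Q2 numeric(1), cross-validated predictive fraction (NA until computed).
#' @slot nOrth integer(1), number of orthogonal components.
#' @export
setClass("OPLSDAModel",
  contains = "MultivariateModel",
  representation(
    scoresOrth = "matrix",
    weights = "numeric",
    weightsOrth = "matrix",
    loadingsOrth = "matrix",
    coef = "numeric",
    yMean = "numeric",
    y = "numeric",
    classes = "character",
    R2Y = "numeric",
    Q2 = "numeric",
    nOrth = "integer"
  )
)

setValidity("OPLSDAModel", function(object) {
  msg <- character()
  if (any(object@R2X < -1e-12 | object@R2X > 1 + 1e-12))
    msg <- c(msg, "each R2X must lie in [0, 1]")
  t <- object@scores[, 1]
  if (ncol(object@scoresOrth) > 0) {
    to <- scale(object@scoresOrth, center = TRUE, scale = FALSE)
    tc <- t - mean(t)
    if (max(abs(crossprod(tc, to))) > 1e-6 * sqrt(sum(tc^2)))
      msg <- c(msg, "predictive score must be orthogonal to orthogonal scores")
  }
  if (length(msg)) msg else TRUE
})

#' Pathway library
#'
#' File-based stand-in for an online pathway resource: per pathway, the member
#' compound identifiers (KEGG style), member protein identifiers, and an edge
#' list on the compound members used for topology impact.
#'
#' @slot pathways data.frame with columns `pathway_id`, `name`.
#' @slot compounds named list (by pathway_id) of compound member ids.
#' @slot proteins named list (by pathway_id) of protein member ids.
#' @slot edges named list (by pathway_id) of two-column compound edge matrices.
#' @slot provenance character(1).
#' @export
setClass("PathwayLibrary",
  representation(
    pathways = "data.frame",
    compounds = "list",
    proteins = "list",
    edges = "list",
    provenance = "character"
  )
)

setValidity("PathwayLibrary", function(object) {
  msg <- character()
  ids <- object@pathways$pathway_id
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "pathway ids must be present and unique")
  keys <- canonicalizeName(object@pathways$name)
  if (anyDuplicated(keys))
    msg <- c(msg, "pathway names must be unique after canonicalization")
  for (id in ids) {
    cm <- object@compounds[[id]]
    if (length(cm) == 0)
      msg <- c(msg, sprintf("pathway %s has no compound members", id))
    e <- object@edges[[id]]
    if (!is.null(e) && length(e) && !all(as.vector(e) %in% cm))
      msg <- c(msg, sprintf("pathway %s has edge endpoints outside members", id))
  }
  if (length(msg)) head(msg, 5) else TRUE
})

#' Herb-compound-protein-pathway network
#'
#' The typed, layered network produced by reverse-mapping overlapping pathways
#' back to target proteins, active compounds and herbs. Node tiers are stored
#' as an igraph vertex attribute `tier`; degrees are computed on the induced
#' subgraph only.
#'
#' @slot graph an igraph object with vertex attributes `tier` and `degree`.
#' @slot tiers named integer vector of node counts per tier.
#' @export
setClass("CompoundTargetNetwork",
  representation(graph = "ANY", tiers = "integer")
)

setValidity("CompoundTargetNetwork", function(object) {
  if (!igraph::is_igraph(object@graph)) return("graph must be an igraph object")
  tier <- igraph::V(object@graph)$tier
  ok <- c("herb", "compound", "protein", "pathway")
  if (!all(tier %in% ok))
    return("vertex tiers must be herb/compound/protein/pathway")
  el <- igraph::as_edgelist(object@graph)
  if (nrow(el)) {
    lv <- match(tier, ok)
    names(lv) <- igraph::V(object@graph)$name
    if (any(abs(lv[el[, 1]] - lv[el[, 2]]) != 1L))
      return("edges must join adjacent tiers")
  }
  TRUE
})
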