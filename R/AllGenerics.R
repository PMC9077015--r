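#' Accessors for model and container classes
#'
#' @param object a pharmetab S4 object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scores", function(object, ...) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("loadings2", function(object, ...) standardGeneric("loadings2"))

#' @rdname accessors
#' @export
setGeneric("r2x", function(object, ...) standardGeneric("r2x"))

#' @rdname accessors
#' @export
setGeneric("r2y", function(object, ...) standardGeneric("r2y"))

#' @rdname accessors
#' @export
setGeneric("q2", function(object, ...) standardGeneric("q2"))

#' @rdname accessors
#' @export
setGeneric("bucketPPM", function(object, ...) standardGeneric("bucketPPM"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(object, ...) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("bucketValues", function(object, ...) standardGeneric("bucketValues"))

#' @rdname accessors
#' @export
setGeneric("pathwayIds", function(object, ...) standardGeneric("pathwayIds"))

#' @rdname accessors
#' @export
setGeneric("pathwayNames", function(object, ...) standardGeneric("pathwayNames"))

#' @rdname accessors
#' @export
setGeneric("pathwayCompounds", function(object, ...) standardGeneric("pathwayCompounds"))

#' @rdname accessors
#' @export
setGeneric("pathwayProteins", function(object, ...) standardGeneric("pathwayProteins"))

#' @rdname accessors
#' @export
setGeneric("pathwayEdges", function(object, ...) standardGeneric("pathwayEdges"))

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(object, ...) standardGeneric("networkGraph"))

#' @rdname accessors
#' @export
setGeneric("tierCounts", function(object, ...) standardGeneric("tierCounts"))

# -- methods ------------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("scores", "MultivariateModel", function(object, ...) object@scores)

#' @rdname accessors
#' @export
setMethod("loadings2", "MultivariateModel", function(object, ...) object@loadings)

#' @rdname accessors
#' @export
setMethod("r2x", "MultivariateModel", function(object, ...) object@R2X)

#' @rdname accessors
#' @export
setMethod("r2y", "OPLSDAModel", function(object, ...) object@R2Y)

#' @rdname accessors
#' @export
setMethod("q2", "OPLSDAModel", function(object, ...) object@Q2)

#' @rdname accessors
#' @export
setMethod("bucketPPM", "NMRBucketMatrix", function(object, ...)
  SummarizedExperiment::rowData(object)$ppm)

#' @rdname accessors
#' @export
setMethod("groupLabels", "NMRBucketMatrix", function(object, ...)
  as.character(SummarizedExperiment::colData(object)$group))

#' @rdname accessors
#' @export
setMethod("groupLabels", "SpectrumSet", function(object, ...)
  vapply(object@spectra, function(s) s@group, character(1)))

#' Samples-by-buckets matrix of normalized integrals
#' @rdname accessors
#' @export
setMethod("bucketValues", "NMRBucketMatrix", function(object, ...)
  t(SummarizedExperiment::assay(object)))

#' @rdname accessors
#' @export
setMethod("pathwayIds", "PathwayLibrary", function(object, ...)
  object@pathways$pathway_id)

#' @rdname accessors
#' @export
setMethod("pathwayNames", "PathwayLibrary", function(object, ...)
  setNames(object@pathways$name, object@pathways$pathway_id))

#' @rdname accessors
#' @export
setMethod("pathwayCompounds", "PathwayLibrary", function(object, ...) object@compounds)

#' @rdname accessors
#' @export
setMethod("pathwayProteins", "PathwayLibrary", function(object, ...) object@proteins)

#' @rdname accessors
#' @export
setMethod("pathwayEdges", "PathwayLibrary", function(object, ...) object@edges)

#' @rdname accessors
#' @export
setMethod("networkGraph", "CompoundTargetNetwork", function(object, ...) object@graph)

#' @rdname accessors
#' @export
setMethod("tierCounts", "CompoundTargetNetwork", function(object, ...) object@tiers)

# -- show ---------------------------------------------------------------------

setMethod("show", "NMRSpectrum", function(object) {
  cat(sprintf(
    "NMRSpectrum '%s' (%s): %d points, delta %.3f..%.3f ppm\n",
    object@sampleId, object@group, length(object@ppm),
    min(object@ppm), max(object@ppm)
  ))
})

setMethod("show", "SpectrumSet", function(object) {
  g <- table(object@manifest$group)
  cat(sprintf(
    "SpectrumSet: %d spectra (%s)\n", length(object@spectra),
    paste(sprintf("%s n=%d", names(g), as.integer(g)), collapse = ", ")
  ))
})

setMethod("show", "BucketSpec", function(object) {
  cat(sprintf(
    "BucketSpec: %.4g-ppm buckets on [%.3g, %.3g], %d exclusion(s), ref %s at %.3f\n",
    object@width, object@region[1], object@region[2],
    length(object@exclusions), object@referencePattern, object@referencePPM
  ))
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf(
    "PCAModel: %d components over %d variables; cumulative R2X = %.3f\n",
    ncol(object@scores), nrow(object@loadings), sum(object@R2X)
  ))
})

setMethod("show", "OPLSDAModel", function(object) {
  cat(sprintf(
    "OPLSDAModel (%s vs %s): 1 predictive + %d orthogonal; R2X = %.3f, R2Y = %.3f, Q2 = %s\n",
    object@classes[1], object@classes[2], object@nOrth,
    sum(object@R2X), object@R2Y,
    if (is.na(object@Q2)) "not computed" else sprintf("%.3f", object@Q2)
  ))
})

setMethod("show", "PathwayLibrary", function(object) {
  cat(sprintf(
    "PathwayLibrary (%s): %d pathways, %d distinct compounds, %d distinct proteins\n",
    object@provenance, nrow(object@pathways),
    length(unique(unlist(object@compounds))),
    length(unique(unlist(object@proteins)))
  ))
})

setMethod("show", "CompoundTargetNetwork", function(object) {
  tc <- object@tiers
  cat(sprintf(
    "CompoundTargetNetwork: %s; %d edges\n",
    paste(sprintf("%d %ss", as.integer(tc), names(tc)), collapse = ", "),
    igraph::ecount(object@graph)
  ))
})
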