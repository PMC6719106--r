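#' Accessors
#'
#' Small accessor generics for the package's central objects; user code
#' should use these rather than reaching into slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))

#' @rdname accessors
#' @export
setGeneric("log2Fpkm", function(x) standardGeneric("log2Fpkm"))

#' @rdname accessors
#' @export
setGeneric("stageOf", function(x) standardGeneric("stageOf"))

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setGeneric("moduleEigengenes", function(x) standardGeneric("moduleEigengenes"))

#' @rdname accessors
#' @export
setGeneric("traitStats", function(x) standardGeneric("traitStats"))

#' @rdname accessors
#' @export
setGeneric("temporalClasses", function(x) standardGeneric("temporalClasses"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("networkDegree", function(x) standardGeneric("networkDegree"))

#' @rdname accessors
#' @export
setGeneric("exonsBy", function(x) standardGeneric("exonsBy"))

#' @rdname accessors
#' @export
setGeneric("geneSpans", function(x) standardGeneric("geneSpans"))

#' @rdname accessors
#' @export
setGeneric("transcriptMeta", function(x) standardGeneric("transcriptMeta"))

#' @rdname accessors
#' @export
setMethod("fpkm", "StageExpression", function(x)
    SummarizedExperiment::assay(x, "fpkm"))

#' @rdname accessors
#' @export
setMethod("log2Fpkm", "StageExpression", function(x)
    log2(SummarizedExperiment::assay(x, "fpkm") + 1))

#' @rdname accessors
#' @export
setMethod("stageOf", "StageExpression", function(x)
    SummarizedExperiment::colData(x)$stage)

#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModuleSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("moduleEigengenes", "ModuleSet", function(x) x@eigengenes)

#' @rdname accessors
#' @export
setMethod("traitStats", "ModuleSet", function(x) x@traitStats)

#' @rdname accessors
#' @export
setMethod("temporalClasses", "ModuleSet", function(x) x@temporalClass)

#' @rdname accessors
#' @export
setMethod("networkEdges", "TargetNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("networkDegree", "TargetNetwork", function(x) x@degree)

#' @rdname accessors
#' @export
setMethod("exonsBy", "TranscriptAnnotation", function(x) x@exons)

#' @rdname accessors
#' @export
setMethod("geneSpans", "TranscriptAnnotation", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("transcriptMeta", "TranscriptAnnotation", function(x) x@txMeta)
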