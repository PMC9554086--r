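#' @rdname Repertoire-accessors
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))

#' @rdname Repertoire-accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname Repertoire-accessors
#' @export
setGeneric("cohort", function(x) standardGeneric("cohort"))

#' @rdname Repertoire-accessors
#' @export
setGeneric("tissue", function(x) standardGeneric("tissue"))

#' @rdname Repertoire-accessors
#' @export
setGeneric("cellFraction", function(x) standardGeneric("cellFraction"))

#' @rdname Repertoire-accessors
#' @export
setGeneric("clonotypes", function(x) standardGeneric("clonotypes"))

#' @rdname CellRecord-accessors
#' @export
setGeneric("barcode", function(x) standardGeneric("barcode"))

#' @rdname CellRecord-accessors
#' @export
setGeneric("alphaChains", function(x) standardGeneric("alphaChains"))

#' @rdname CellRecord-accessors
#' @export
setGeneric("betaChains", function(x) standardGeneric("betaChains"))

#' @rdname CellRecord-accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
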