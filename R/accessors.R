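#' Accessors for DomainScope classes
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param x A DomainScope object.
#' @return `proteinId`/`domainId`/`domainSource` return strings;
#'   `domainRanges` a [SegmentList-class]; `proteinLength` an integer;
#'   `caCoords`/`paeMatrix` matrices; `plddtScores`/`sseLabels` vectors or
#'   `NULL`; `meanInternalProb` a number in \[0, 1\].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))
#' @rdname accessors
#' @export
setGeneric("domainId", function(x) standardGeneric("domainId"))
#' @rdname accessors
#' @export
setGeneric("domainSource", function(x) standardGeneric("domainSource"))
#' @rdname accessors
#' @export
setGeneric("domainRanges", function(x) standardGeneric("domainRanges"))
#' @rdname accessors
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))
#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))
#' @rdname accessors
#' @export
setGeneric("paeMatrix", function(x) standardGeneric("paeMatrix"))
#' @rdname accessors
#' @export
setGeneric("plddtScores", function(x) standardGeneric("plddtScores"))
#' @rdname accessors
#' @export
setGeneric("sseLabels", function(x) standardGeneric("sseLabels"))
#' @rdname accessors
#' @export
setGeneric("meanInternalProb", function(x) standardGeneric("meanInternalProb"))

#' @rdname accessors
#' @export
setMethod("proteinId", "DomainAnnotation", function(x) x@proteinId)
#' @rdname accessors
#' @export
setMethod("proteinId", "ProteinModel", function(x) x@proteinId)
#' @rdname accessors
#' @export
setMethod("domainId", "DomainAnnotation", function(x) x@domainId)
#' @rdname accessors
#' @export
setMethod("domainSource", "DomainAnnotation", function(x) x@source)
#' @rdname accessors
#' @export
setMethod("domainRanges", "DomainAnnotation", function(x) x@ranges)
#' @rdname accessors
#' @export
setMethod("domainRanges", "ParsedDomain", function(x) x@ranges)
#' @rdname accessors
#' @export
setMethod("proteinLength", "ProteinModel", function(x) nrow(x@caCoords))
#' @rdname accessors
#' @export
setMethod("caCoords", "ProteinModel", function(x) x@caCoords)
#' @rdname accessors
#' @export
setMethod("paeMatrix", "ProteinModel", function(x) x@pae)
#' @rdname accessors
#' @export
setMethod("plddtScores", "ProteinModel",
          function(x) if (length(x@plddt)) x@plddt else NULL)
#' @rdname accessors
#' @export
setMethod("sseLabels", "ProteinModel",
          function(x) if (length(x@sse)) x@sse else NULL)
#' @rdname accessors
#' @export
setMethod("meanInternalProb", "ParsedDomain", function(x) x@meanInternalProb)
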