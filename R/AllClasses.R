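#' @import methods
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors isSorted
NULL

#' SegmentList: an ordered set of residue intervals
#'
#' The universal representation of a (possibly discontinuous) protein domain:
#' a sorted list of disjoint, non-adjacent, 1-based inclusive residue
#' intervals. Overlapping or adjacent intervals supplied to the constructor
#' are merged, because a segment list denotes a residue *set*, not
#' bookkeeping about how it was written down.
#'
#' @slot ranges An [IRanges::IRanges] holding the normalized intervals.
#'
#' @seealso [parseRangeString()], [formatRangeString()], [totalLength()],
#'   [intersectionSize()]
#' @export
setClass("SegmentList", representation(ranges = "IRanges"))

setValidity("SegmentList", function(object) {
    ir <- object@ranges
    if (length(ir) == 0L)
        return("SegmentList must contain at least one residue")
    if (any(IRanges::start(ir) < 1L))
        return("residue indices are 1-based; start < 1 found")
    if (any(IRanges::width(ir) < 1L))
        return("every segment must satisfy end >= start")
    if (length(ir) > 1L) {
        s <- IRanges::start(ir)
        e <- IRanges::end(ir)
        if (is.unsorted(s))
            return("segments must be sorted by start")
        if (any(s[-1L] - e[-length(e)] < 2L))
            return("segments must be disjoint and non-adjacent")
    }
    TRUE
})

#' Construct a SegmentList
#'
#' @param start,end Integer vectors of equal length: 1-based inclusive
#'   interval bounds. Overlapping and adjacent intervals are merged.
#' @return A [SegmentList-class] object.
#' @examples
#' SegmentList(c(198, 282), c(234, 371))
#' SegmentList(c(5, 11), c(10, 12))  # adjacent -> merged to 5-12
#' @export
SegmentList <- function(start, end = start) {
    start <- as.integer(start)
    end <- as.integer(end)
    if (length(start) != length(end) || length(start) == 0L)
        stop("start and end must be non-empty vectors of equal length")
    if (any(is.na(start)) || any(is.na(end)))
        stop("NA residue bounds are not allowed")
    if (any(end < start))
        stop("reversed interval: end < start for segment ",
             paste0(start[end < start][1L], "-", end[end < start][1L]))
    ir <- IRanges::reduce(IRanges(start = start, end = end))
    new("SegmentList", ranges = ir)
}

#' @describeIn SegmentList Display a SegmentList as its range string.
#' @param object A SegmentList.
#' @export
setMethod("show", "SegmentList", function(object) {
    cat("SegmentList:", formatRangeString(object),
        sprintf("(%d residues in %d segment%s)\n", totalLength(object),
                nSegments(object), if (nSegments(object) == 1L) "" else "s"))
})

#' DomainAnnotation: one domain of one protein, with provenance
#'
#' Binds a [SegmentList-class] to a protein identifier, a domain identifier
#' and a source label saying which segmentation produced it (`"dpam"` for
#' the PAE-based parser, `"ted"` for the alternative structure-based
#' chopping, `"truth"` for synthetic ground truth).
#'
#' @slot proteinId Protein identifier.
#' @slot domainId Domain identifier, unique within (protein, source).
#' @slot ranges The domain's residue intervals as a [SegmentList-class].
#' @slot source One of `"dpam"`, `"ted"`, `"truth"`.
#' @export
setClass("DomainAnnotation", representation(
    proteinId = "character",
    domainId = "character",
    ranges = "SegmentList",
    source = "character"))

.domainSources <- c("dpam", "ted", "truth")

setValidity("DomainAnnotation", function(object) {
    if (length(object@proteinId) != 1L || !nzchar(object@proteinId))
        return("proteinId must be a single non-empty string")
    if (length(object@domainId) != 1L || !nzchar(object@domainId))
        return("domainId must be a single non-empty string")
    if (length(object@source) != 1L || !object@source %in% .domainSources)
        return(paste0("source must be one of: ",
                      paste(.domainSources, collapse = ", ")))
    TRUE
})

#' Construct a DomainAnnotation
#'
#' @param proteinId,domainId Identifier strings.
#' @param ranges A [SegmentList-class], or a range string parsed with
#'   [parseRangeString()].
#' @param source One of `"dpam"`, `"ted"`, `"truth"`.
#' @return A [DomainAnnotation-class].
#' @examples
#' DomainAnnotation("S0G0I7", "TED02", "198-234,282-371", "ted")
#' @export
DomainAnnotation <- function(proteinId, domainId, ranges, source) {
    if (is.character(ranges))
        ranges <- parseRangeString(ranges)
    new("DomainAnnotation", proteinId = as.character(proteinId),
        domainId = as.character(domainId), ranges = ranges,
        source = as.character(source))
}

#' @describeIn DomainAnnotation Display a DomainAnnotation.
#' @param object A DomainAnnotation.
#' @export
setMethod("show", "DomainAnnotation", function(object) {
    cat(sprintf("DomainAnnotation %s/%s [%s]: %s (%d residues)\n",
                object@proteinId, object@domainId, object@source,
                formatRangeString(object@ranges), totalLength(object@ranges)))
})

#' ProteinModel: a predicted structure reduced to parser inputs
#'
#' Holds everything the domain parser consumes for one protein: CA
#' coordinates, the predicted aligned error (PAE) matrix, and optional
#' per-residue pLDDT scores and secondary-structure labels.
#'
#' @slot proteinId Protein identifier.
#' @slot caCoords length x 3 numeric matrix of CA coordinates in Angstrom.
#' @slot pae length x length PAE matrix in Angstrom, values in \[0, 35\].
#'   Need not be symmetric; the parser symmetrizes it.
#' @slot plddt Optional per-residue confidence in \[0, 100\] (length 0 if
#'   absent).
#' @slot sse Optional per-residue secondary-structure labels in
#'   \{H, E, C\} (length 0 if absent).
#' @export
setClass("ProteinModel", representation(
    proteinId = "character",
    caCoords = "matrix",
    pae = "matrix",
    plddt = "numeric",
    sse = "character"))

setValidity("ProteinModel", function(object) {
    n <- nrow(object@caCoords)
    if (n < 1L)
        return("model must contain at least one residue")
    if (ncol(object@caCoords) != 3L)
        return("caCoords must have 3 columns (x, y, z)")
    if (nrow(object@pae) != n || ncol(object@pae) != n)
        return(sprintf("PAE matrix is %dx%d but the model has %d residues",
                       nrow(object@pae), ncol(object@pae), n))
    if (any(object@pae < 0) || any(object@pae > 35))
        return("PAE values must lie in [0, 35] Angstrom")
    sym <- (object@pae + t(object@pae)) / 2
    if (any(diag(sym) > 1))
        return("PAE diagonal must be ~0 after symmetrization (tolerance 1 A)")
    if (length(object@plddt) &&
        (length(object@plddt) != n || any(object@plddt < 0) ||
         any(object@plddt > 100)))
        return("plddt must be per-residue values in [0, 100]")
    if (length(object@sse) &&
        (length(object@sse) != n || !all(object@sse %in% c("H", "E", "C"))))
        return("sse must be per-residue labels in {H, E, C}")
    TRUE
})

#' Construct a ProteinModel
#'
#' @param proteinId Identifier string.
#' @param caCoords length x 3 matrix of CA coordinates (Angstrom).
#' @param pae length x length PAE matrix (Angstrom).
#' @param plddt Optional per-residue pLDDT in \[0, 100\].
#' @param sse Optional per-residue labels in \{H, E, C\}.
#' @return A [ProteinModel-class].
#' @export
ProteinModel <- function(proteinId, caCoords, pae, plddt = NULL, sse = NULL) {
    new("ProteinModel", proteinId = as.character(proteinId),
        caCoords = as.matrix(caCoords), pae = as.matrix(pae),
        plddt = if (is.null(plddt)) numeric(0) else as.numeric(plddt),
        sse = if (is.null(sse)) character(0) else as.character(sse))
}

#' @describeIn ProteinModel Display a ProteinModel.
#' @param object A ProteinModel.
#' @export
setMethod("show", "ProteinModel", function(object) {
    cat(sprintf("ProteinModel %s: %d residues%s%s\n", object@proteinId,
                nrow(object@caCoords),
                if (length(object@plddt)) ", pLDDT" else "",
                if (length(object@sse)) ", SSE" else ""))
})

#' ParsedDomain: one domain emitted by the parser
#'
#' @slot ranges The domain's residues as a [SegmentList-class].
#' @slot meanInternalProb Mean same-domain probability over all ordered
#'   residue pairs inside the domain; a crude cohesion score in \[0, 1\].
#' @export
setClass("ParsedDomain", representation(
    ranges = "SegmentList",
    meanInternalProb = "numeric"))

setValidity("ParsedDomain", function(object) {
    p <- object@meanInternalProb
    if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
        return("meanInternalProb must be a single value in [0, 1]")
    TRUE
})

#' @describeIn ParsedDomain Display a ParsedDomain.
#' @param object A ParsedDomain.
#' @export
setMethod("show", "ParsedDomain", function(object) {
    cat(sprintf("ParsedDomain: %s (%d residues, cohesion %.3f)\n",
                formatRangeString(object@ranges), totalLength(object@ranges),
                object@meanInternalProb))
})
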