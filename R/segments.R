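#' Parse a residue range string into a SegmentList
#'
#' Residue ranges are written the way the domain literature prints them:
#' comma-separated `"a-b"` intervals (1-based, inclusive), e.g.
#' `"198-234,282-371"` for a discontinuous domain. Single residues may be
#' given as a bare number. Both ASCII hyphens and en-dashes are accepted as
#' interval separators. Whitespace around tokens is ignored. Overlapping or
#' adjacent intervals are merged during normalization.
#'
#' @param text A range expression such as `"198-234,282-371"`.
#' @return A [SegmentList-class].
#' @examples
#' parseRangeString("198-234,282-371")  # 127 residues
#' parseRangeString("1-370")
#' parseRangeString("5-10,11-12")       # adjacent -> "5-12"
#' @export
parseRangeString <- function(text) {
    if (length(text) != 1L || is.na(text))
        stop("range string must be a single character value")
    text <- gsub("–|−", "-", text)   # en-dash / minus -> hyphen
    tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
    if (length(tokens) == 0L || !any(nzchar(tokens)))
        stop("empty range string")
    starts <- integer(length(tokens))
    ends <- integer(length(tokens))
    for (k in seq_along(tokens)) {
        tok <- tokens[k]
        if (grepl("^[0-9]+$", tok)) {
            starts[k] <- ends[k] <- as.integer(tok)
        } else if (grepl("^[0-9]+\\s*-\\s*[0-9]+$", tok)) {
            ab <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1L]])
            if (ab[2L] < ab[1L])
                stop("reversed interval in token '", tok, "'")
            starts[k] <- ab[1L]
            ends[k] <- ab[2L]
        } else {
            stop("malformed range token '", tok, "'")
        }
    }
    SegmentList(starts, ends)
}

#' Format a SegmentList as a range string
#'
#' Inverse of [parseRangeString()] on normalized segment lists:
#' `parseRangeString(formatRangeString(x))` recovers `x`.
#'
#' @param x A [SegmentList-class].
#' @return A single string such as `"198-234,282-371"`.
#' @export
formatRangeString <- function(x) {
    stopifnot(is(x, "SegmentList"))
    paste(paste0(IRanges::start(x@ranges), "-", IRanges::end(x@ranges)),
          collapse = ",")
}

#' @rdname accessors
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname accessors
#' @export
setMethod("totalLength", "SegmentList",
          function(x) sum(IRanges::width(x@ranges)))

#' @rdname accessors
#' @export
setMethod("totalLength", "DomainAnnotation",
          function(x) totalLength(x@ranges))

#' Number of segments in a SegmentList
#'
#' @param x A [SegmentList-class].
#' @return Integer count of (normalized) segments.
#' @export
nSegments <- function(x) {
    stopifnot(is(x, "SegmentList"))
    length(x@ranges)
}

#' Explicit residue set of a SegmentList
#'
#' @param x A [SegmentList-class].
#' @return Sorted integer vector of every residue index in the list.
#' @export
residueSet <- function(x) {
    stopifnot(is(x, "SegmentList"))
    as.integer(unlist(mapply(seq.int, IRanges::start(x@ranges),
                             IRanges::end(x@ranges), SIMPLIFY = FALSE),
                      use.names = FALSE))
}

#' Build a SegmentList from an explicit residue set
#'
#' @param residues Integer vector of residue indices (any order, duplicates
#'   allowed).
#' @return A [SegmentList-class] covering exactly those residues.
#' @export
segmentsFromResidues <- function(residues) {
    residues <- sort(unique(as.integer(residues)))
    if (length(residues) == 0L)
        stop("cannot build a SegmentList from an empty residue set")
    brk <- c(0L, which(diff(residues) > 1L), length(residues))
    SegmentList(residues[brk[-length(brk)] + 1L], residues[brk[-1L]])
}

#' Interval bounds of a SegmentList
#'
#' @param x A [SegmentList-class].
#' @return A two-column integer matrix with columns `start` and `end`.
#' @export
segmentBounds <- function(x) {
    stopifnot(is(x, "SegmentList"))
    cbind(start = IRanges::start(x@ranges), end = IRanges::end(x@ranges))
}

#' Number of residues shared by two SegmentLists
#'
#' Computed by interval sweep on the normalized intervals; equal to the
#' cardinality of the intersection of the two explicit residue sets.
#'
#' @param a,b [SegmentList-class] objects.
#' @return Integer count of shared residues.
#' @examples
#' intersectionSize(parseRangeString("1-370"),
#'                  parseRangeString("198-234,282-371"))  # 126
#' @export
intersectionSize <- function(a, b) {
    stopifnot(is(a, "SegmentList"), is(b, "SegmentList"))
    sum(IRanges::width(IRanges::intersect(a@ranges, b@ranges)))
}

#' Set difference of two SegmentLists
#'
#' @param a,b [SegmentList-class] objects.
#' @return A [SegmentList-class] of the residues of `a` not in `b`, or
#'   `NULL` when `b` covers all of `a`.
#' @export
segmentDifference <- function(a, b) {
    stopifnot(is(a, "SegmentList"), is(b, "SegmentList"))
    d <- IRanges::setdiff(a@ranges, b@ranges)
    if (length(d) == 0L)
        return(NULL)
    SegmentList(IRanges::start(d), IRanges::end(d))
}

#' Intersection of two SegmentLists
#'
#' @param a,b [SegmentList-class] objects.
#' @return A [SegmentList-class] of shared residues, or `NULL` when the
#'   lists are disjoint.
#' @export
segmentIntersection <- function(a, b) {
    stopifnot(is(a, "SegmentList"), is(b, "SegmentList"))
    d <- IRanges::intersect(a@ranges, b@ranges)
    if (length(d) == 0L)
        return(NULL)
    SegmentList(IRanges::start(d), IRanges::end(d))
}

#' Union of two SegmentLists
#'
#' @param a,b [SegmentList-class] objects.
#' @return A [SegmentList-class] covering the residues of both.
#' @export
segmentUnion <- function(a, b) {
    stopifnot(is(a, "SegmentList"), is(b, "SegmentList"))
    u <- IRanges::union(a@ranges, b@ranges)
    SegmentList(IRanges::start(u), IRanges::end(u))
}
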