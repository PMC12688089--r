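#' Dual overlap fractions between two domains
#'
#' For a parser-side (`dpam`) domain and an alternative-side (`ted`)
#' domain of the same protein, the overlap is quantified in both
#' directions: `f_dpam` = shared residues / dpam length, `f_ted` = shared
#' residues / ted length. A short domain embedded in a long one has a high
#' fraction on its own side and a low one on the other.
#'
#' @param dpam,ted [DomainAnnotation-class] objects (or bare
#'   [SegmentList-class]s).
#' @return Named numeric vector `c(intersection = , f_dpam = , f_ted = )`.
#' @examples
#' overlapFractions(parseRangeString("1-370"),
#'                  parseRangeString("198-234,282-371"))
#' @export
overlapFractions <- function(dpam, ted) {
    a <- if (is(dpam, "DomainAnnotation")) domainRanges(dpam) else dpam
    b <- if (is(ted, "DomainAnnotation")) domainRanges(ted) else ted
    if (is(dpam, "DomainAnnotation") && is(ted, "DomainAnnotation") &&
        proteinId(dpam) != proteinId(ted))
        stop("overlap fractions are defined within one protein")
    inter <- intersectionSize(a, b)
    c(intersection = inter,
      f_dpam = inter / totalLength(a),
      f_ted = inter / totalLength(b))
}

# strict fraction/threshold comparisons in exact integer arithmetic:
# num/den > p  and  num/den < p  for a rational threshold p
.fracGT <- function(num, den, p) num > den * p + 1e-9 * den
.fracLT <- function(num, den, p) num < den * p - 1e-9 * den

#' Significance filter for a domain pair
#'
#' A pair enters the comparison only when either overlap fraction exceeds
#' `overlap_significant` (strictly).
#'
#' @param f_dpam,f_ted Overlap fractions in \[0, 1\].
#' @param th A [defaultThresholds()].
#' @return Logical.
#' @export
isSignificant <- function(f_dpam, f_ted, th = defaultThresholds()) {
    f_dpam > th$overlap_significant | f_ted > th$overlap_significant
}

#' Overlap category of a domain pair
#'
#' * `consistent`: both fractions above `overlap_high` -- the two
#'   segmentations agree on this domain.
#' * `ted_embedded`: `f_ted` above `overlap_high` and `f_dpam` below
#'   `overlap_low` -- the ted domain sits inside a larger dpam domain.
#' * `dpam_embedded`: the mirror image.
#' * `intermediate`: everything else (partial overlaps, boundary values).
#'
#' All inequalities are strict; boundary values fall to `intermediate`.
#'
#' @param f_dpam,f_ted Overlap fractions in \[0, 1\] (vectorized).
#' @param th A [defaultThresholds()].
#' @return Character vector of categories.
#' @examples
#' categorizeOverlap(0.341, 0.992)  # "ted_embedded"
#' categorizeOverlap(0.9, 0.9)      # "consistent"
#' categorizeOverlap(0.8, 0.8)      # "intermediate" (strict boundaries)
#' @export
categorizeOverlap <- function(f_dpam, f_ted, th = defaultThresholds()) {
    if (any(f_dpam < 0 | f_dpam > 1 | f_ted < 0 | f_ted > 1))
        stop("overlap fractions must lie in [0, 1]")
    ifelse(f_dpam > th$overlap_high & f_ted > th$overlap_high, "consistent",
    ifelse(f_ted > th$overlap_high & f_dpam < th$overlap_low, "ted_embedded",
    ifelse(f_dpam > th$overlap_high & f_ted < th$overlap_low, "dpam_embedded",
           "intermediate")))
}

# category from integer counts, avoiding float boundaries entirely
.categorizeExact <- function(inter, dlen, tlen, th) {
    if (.fracGT(inter, dlen, th$overlap_high) &&
        .fracGT(inter, tlen, th$overlap_high)) return("consistent")
    if (.fracGT(inter, tlen, th$overlap_high) &&
        .fracLT(inter, dlen, th$overlap_low)) return("ted_embedded")
    if (.fracGT(inter, dlen, th$overlap_high) &&
        .fracLT(inter, tlen, th$overlap_low)) return("dpam_embedded")
    "intermediate"
}

#' Pair the domains of one protein across two segmentations
#'
#' Each ted-side domain is matched to the dpam-side domain with which it
#' shares the most residues (ties broken toward the dpam domain with the
#' smaller first residue). Pairs failing the significance filter
#' ([isSignificant()]) are dropped. A ted domain therefore appears in at
#' most one pair; a dpam domain may appear in several. Threshold
#' comparisons are made on exact integer counts, so boundary fractions
#' like 4/5 are classified unambiguously.
#'
#' @param dpamList,tedList Lists of [DomainAnnotation-class] from one
#'   protein.
#' @param th A [defaultThresholds()].
#' @return Data frame with columns `protein_id`, `dpam_id`, `ted_id`,
#'   `intersection`, `f_dpam`, `f_ted`, `category` (zero rows when nothing
#'   overlaps significantly).
#' @export
pairDomains <- function(dpamList, tedList, th = defaultThresholds()) {
    empty <- data.frame(protein_id = character(0), dpam_id = character(0),
                        ted_id = character(0), intersection = integer(0),
                        f_dpam = numeric(0), f_ted = numeric(0),
                        category = character(0), stringsAsFactors = FALSE)
    if (length(dpamList) == 0L || length(tedList) == 0L)
        return(empty)
    dfirst <- vapply(dpamList, function(d)
        segmentBounds(domainRanges(d))[1L, 1L], integer(1))
    rows <- list()
    for (tdom in tedList) {
        tl <- domainRanges(tdom)
        inters <- vapply(dpamList, function(d)
            intersectionSize(domainRanges(d), tl), integer(1))
        if (max(inters) == 0L)
            next
        best <- which(inters == max(inters))
        i <- best[which.min(dfirst[best])]
        dlen <- totalLength(domainRanges(dpamList[[i]]))
        tlen <- totalLength(tl)
        inter <- inters[i]
        sig <- .fracGT(inter, dlen, th$overlap_significant) ||
               .fracGT(inter, tlen, th$overlap_significant)
        if (!sig)
            next
        rows[[length(rows) + 1L]] <- data.frame(
            protein_id = proteinId(tdom),
            dpam_id = domainId(dpamList[[i]]),
            ted_id = domainId(tdom),
            intersection = inter,
            f_dpam = inter / dlen,
            f_ted = inter / tlen,
            category = .categorizeExact(inter, dlen, tlen, th),
            stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(empty)
    do.call(rbind, rows)
}

#' Compare two choppings across a cohort
#'
#' Splits both annotation lists by protein, pairs domains within each
#' shared protein ([pairDomains()]), and stacks the results in a
#' deterministic order (protein id, then ted domain id). Proteins present
#' on only one side are reported with a message and skipped.
#'
#' @param dpamAnnotations,tedAnnotations Lists of
#'   [DomainAnnotation-class] (any number of proteins).
#' @param th A [defaultThresholds()].
#' @return An overlap-pair data frame (see [pairDomains()]).
#' @export
compareCohort <- function(dpamAnnotations, tedAnnotations,
                          th = defaultThresholds()) {
    dIds <- vapply(dpamAnnotations, proteinId, character(1))
    tIds <- vapply(tedAnnotations, proteinId, character(1))
    shared <- intersect(unique(dIds), unique(tIds))
    lonely <- c(setdiff(unique(dIds), shared), setdiff(unique(tIds), shared))
    if (length(lonely))
        message("skipping protein(s) present on one side only: ",
                paste(lonely, collapse = ", "))
    out <- lapply(sort(shared), function(pid)
        pairDomains(dpamAnnotations[dIds == pid],
                    tedAnnotations[tIds == pid], th))
    out <- do.call(rbind, c(out, list(pairDomains(list(), list(), th))))
    out[order(out$protein_id, out$ted_id), , drop = FALSE]
}
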