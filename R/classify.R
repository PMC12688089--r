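#' Analysis thresholds
#'
#' Every cutoff of the analysis in one place. Printed thresholds are
#' applied strictly in their printed direction ("above 0.9" means `> 0.9`,
#' "less than 0.6" means `< 0.6`); boundary values fall to the
#' intermediate/insignificant side.
#'
#' @param confidence_cut Reference-assignment confidence above which a
#'   domain counts as confidently assigned.
#' @param seqrel_strong Best_Seq_Rel above which sequence evidence is
#'   strong.
#' @param seqrel_low Best_Seq_Rel below which sequence evidence is lacking.
#' @param seqrel_very_low Best_Seq_Rel below which sequence evidence is
#'   essentially absent.
#' @param overlap_high Overlap fraction above which one segmentation
#'   covers the other well.
#' @param overlap_low Overlap fraction below which coverage is poor.
#' @param overlap_significant Either overlap fraction must exceed this for
#'   a domain pair to enter the comparison.
#' @param simple_sse_max Maximum SSE count of a simple-topology domain.
#' @param partial_ratio Domain length over reference length below which a
#'   confident assignment counts as partial ("much longer reference").
#' @param helix_min_run,strand_min_run Minimum run lengths (residues) for
#'   a helix/strand to count as an SSE.
#' @return A named list of class `Thresholds`.
#' @export
defaultThresholds <- function(confidence_cut = 0.9, seqrel_strong = 0.95,
                              seqrel_low = 0.8, seqrel_very_low = 0.1,
                              overlap_high = 0.8, overlap_low = 0.6,
                              overlap_significant = 0.5, simple_sse_max = 2,
                              partial_ratio = 0.5, helix_min_run = 4,
                              strand_min_run = 3) {
    th <- list(confidence_cut = confidence_cut,
               seqrel_strong = seqrel_strong, seqrel_low = seqrel_low,
               seqrel_very_low = seqrel_very_low,
               overlap_high = overlap_high, overlap_low = overlap_low,
               overlap_significant = overlap_significant,
               simple_sse_max = as.integer(simple_sse_max),
               partial_ratio = partial_ratio,
               helix_min_run = as.integer(helix_min_run),
               strand_min_run = as.integer(strand_min_run))
    if (!(th$overlap_low > 0 && th$overlap_low < th$overlap_high &&
          th$overlap_high <= 1))
        stop("need 0 < overlap_low < overlap_high <= 1")
    structure(th, class = c("Thresholds", "list"))
}

.assignmentCategories <- c("well_assigned", "unassigned",
                           "simple_topology", "partial")
.overlapCategories <- c("consistent", "ted_embedded", "dpam_embedded",
                        "intermediate")
.seqrelBins <- c("strong", "intermediate", "low", "very_low")

#' Count secondary-structure elements inside a domain
#'
#' A helix is a maximal run of at least `helix_min_run` consecutive `H`
#' residues inside the domain's ranges; a strand, a run of at least
#' `strand_min_run` consecutive `E` residues. A run interrupted by a range
#' discontinuity is counted piecewise: each piece long enough on its own
#' counts separately.
#'
#' @param sse Per-residue labels in \{H, E, C\} for the whole protein.
#' @param ranges A [SegmentList-class].
#' @param th A [defaultThresholds()].
#' @return Named integer vector `c(n_helix = ..., n_strand = ...)`.
#' @export
countSse <- function(sse, ranges, th = defaultThresholds()) {
    if (is.null(sse) || length(sse) == 0L)
        stop("per-residue SSE labels are required; supply them with the model")
    stopifnot(is(ranges, "SegmentList"))
    if (max(segmentBounds(ranges)[, "end"]) > length(sse))
        stop("ranges exceed the SSE label vector")
    nh <- 0L; ns <- 0L
    b <- segmentBounds(ranges)
    for (k in seq_len(nrow(b))) {
        lab <- sse[b[k, 1L]:b[k, 2L]]
        r <- rle(lab)
        nh <- nh + sum(r$values == "H" & r$lengths >= th$helix_min_run)
        ns <- ns + sum(r$values == "E" & r$lengths >= th$strand_min_run)
    }
    c(n_helix = nh, n_strand = ns)
}

#' Classify one domain into the four assignment categories
#'
#' Categories, in precedence order:
#' 1. `simple_topology` -- at most `simple_sse_max` SSEs in total (one or
#'    two helices/strands), whatever the confidence;
#' 2. `partial` -- confidently assigned (`confidence > confidence_cut`)
#'    but much shorter than its reference
#'    (`length / reference_length < partial_ratio`);
#' 3. `well_assigned` -- confidently assigned otherwise;
#' 4. `unassigned` -- everything else (a globular domain with enough SSEs
#'    that no reference assignment reaches the confidence cut).
#'
#' @param confidence Assignment confidence in \[0, 1\].
#' @param n_helix,n_strand SSE counts (see [countSse()]).
#' @param length Domain length in residues.
#' @param reference_length Length of the matched reference domain;
#'   required when `confidence > confidence_cut`, ignored otherwise.
#' @param th A [defaultThresholds()].
#' @return One of `"well_assigned"`, `"unassigned"`, `"simple_topology"`,
#'   `"partial"`.
#' @export
classifyDomain <- function(confidence, n_helix, n_strand, length,
                           reference_length = NA,
                           th = defaultThresholds()) {
    if (is.na(confidence) || confidence < 0 || confidence > 1)
        stop("confidence must be set and lie in [0, 1]")
    if (is.na(n_helix) || is.na(n_strand) || n_helix < 0 || n_strand < 0)
        stop("SSE counts must be set and non-negative")
    if (n_helix + n_strand <= th$simple_sse_max)
        return("simple_topology")
    if (confidence > th$confidence_cut) {
        if (is.na(reference_length) || reference_length <= 0)
            stop("reference_length must be set for confident assignments")
        if (length / reference_length < th$partial_ratio)
            return("partial")
        return("well_assigned")
    }
    "unassigned"
}

#' Classify every record of a domain table
#'
#' @param records Data frame with columns `confidence`, `n_helix`,
#'   `n_strand`, `length` and `reference_length`.
#' @param th A [defaultThresholds()].
#' @return `records` with a `category` column appended.
#' @export
classifyRecords <- function(records, th = defaultThresholds()) {
    records$category <- vapply(seq_len(nrow(records)), function(i)
        classifyDomain(records$confidence[i], records$n_helix[i],
                       records$n_strand[i], records$length[i],
                       records$reference_length[i], th), character(1))
    records
}

#' Bin a Best_Seq_Rel score
#'
#' `strong` for values above `seqrel_strong` (strict), `intermediate` on
#' `[seqrel_low, seqrel_strong]`, `low` on `[seqrel_very_low, seqrel_low)`,
#' `very_low` below `seqrel_very_low`. The four bins partition \[0, 1\].
#'
#' @param v Best_Seq_Rel value(s) in \[0, 1\].
#' @param th A [defaultThresholds()].
#' @return Character vector of bins.
#' @examples
#' binBestSeqRel(c(0.96, 0.95, 0.5, 0.05))
#' @export
binBestSeqRel <- function(v, th = defaultThresholds()) {
    if (any(is.na(v)) || any(v < 0) || any(v > 1))
        stop("Best_Seq_Rel values must lie in [0, 1]")
    ifelse(v > th$seqrel_strong, "strong",
    ifelse(v >= th$seqrel_low, "intermediate",
    ifelse(v >= th$seqrel_very_low, "low", "very_low")))
}
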