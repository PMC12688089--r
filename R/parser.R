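#' Parser configuration
#'
#' All free parameters of the PAE/distance domain parser in one place.
#'
#' The parser scores each residue pair with a logistic model of three
#' features -- CA--CA distance, symmetrized PAE, and co-alignment support
#' (the fraction of homology-search evidence placing the pair in the same
#' reference domain) -- then average-links 5-residue segments into domains.
#'
#' @param w0 Logistic intercept.
#' @param w_dist,w_pae,w_sup Feature weights (distance and PAE enter with a
#'   negative sign, support with a positive sign).
#' @param dist_scale,pae_scale Feature scales in Angstrom.
#' @param disorder_pae_cutoff Residues whose sequence-local median PAE
#'   exceeds this (Angstrom) are masked as disordered/linker.
#' @param disorder_window Half-width (residues) of the sequence window used
#'   for the disorder median.
#' @param plddt_cutoff Residues with pLDDT below this are masked, when
#'   pLDDT is available.
#' @param segment_size Residues per clustering segment.
#' @param linkage_cutoff Minimum average linkage (probability) for a merge.
#' @param min_domain_size Clusters below this residue count are attached to
#'   their best neighbor or dropped as linker.
#' @return A named list of class `ParserConfig`.
#' @export
parserConfig <- function(w0 = 1, w_dist = 2, w_pae = 2, w_sup = 2,
                         dist_scale = 20, pae_scale = 10,
                         disorder_pae_cutoff = 20, disorder_window = 10,
                         plddt_cutoff = 50, segment_size = 5,
                         linkage_cutoff = 0.5, min_domain_size = 25) {
    cfg <- list(w0 = w0, w_dist = w_dist, w_pae = w_pae, w_sup = w_sup,
                dist_scale = dist_scale, pae_scale = pae_scale,
                disorder_pae_cutoff = disorder_pae_cutoff,
                disorder_window = disorder_window,
                plddt_cutoff = plddt_cutoff,
                segment_size = as.integer(segment_size),
                linkage_cutoff = linkage_cutoff,
                min_domain_size = as.integer(min_domain_size))
    if (cfg$segment_size < 1L)
        stop("segment_size must be >= 1")
    if (cfg$linkage_cutoff <= 0 || cfg$linkage_cutoff >= 1)
        stop("linkage_cutoff must lie in (0, 1)")
    if (cfg$min_domain_size < cfg$segment_size)
        stop("min_domain_size must be >= segment_size")
    if (cfg$dist_scale <= 0 || cfg$pae_scale <= 0)
        stop("feature scales must be positive")
    structure(cfg, class = c("ParserConfig", "list"))
}

#' Symmetrize a PAE matrix
#'
#' PAE is asymmetric (error of residue i when aligned on j differs from the
#' converse); pair features need one value, so the two directions are
#' averaged.
#'
#' @param pae Square numeric matrix.
#' @return Symmetric matrix with entry `(i,j) = mean(pae[i,j], pae[j,i])`.
#' @export
symmetrizePae <- function(pae) {
    pae <- as.matrix(pae)
    if (nrow(pae) != ncol(pae))
        stop("PAE matrix must be square")
    (pae + t(pae)) / 2
}

#' Mask disordered and linker residues
#'
#' A residue is excluded when the median symmetrized PAE between it and its
#' sequence neighbors (within `disorder_window` positions on either side)
#' exceeds `disorder_pae_cutoff`, or when its pLDDT falls below
#' `plddt_cutoff` (if pLDDT is available). A sequence-local window is used
#' rather than the whole row: a residue inside a small domain of a large
#' multi-domain protein has high PAE to most of the chain, but low PAE to
#' its own neighborhood, and only genuinely disordered residues have high
#' error even locally. Included runs shorter than `segment_size` that are
#' flanked by excluded residues (chain termini count as flanking) are
#' absorbed into the mask as linker fragments.
#'
#' @param model A [ProteinModel-class].
#' @param cfg A [parserConfig()].
#' @return Logical vector, `TRUE` = excluded.
#' @export
disorderMask <- function(model, cfg = parserConfig()) {
    stopifnot(is(model, "ProteinModel"))
    pae <- symmetrizePae(paeMatrix(model))
    n <- nrow(pae)
    w <- as.integer(cfg$disorder_window)
    excluded <- vapply(seq_len(n), function(i) {
        nb <- setdiff(max(1L, i - w):min(n, i + w), i)
        if (length(nb) == 0L)
            return(FALSE)
        stats::median(pae[i, nb]) > cfg$disorder_pae_cutoff
    }, logical(1))
    plddt <- plddtScores(model)
    if (!is.null(plddt))
        excluded <- excluded | (plddt < cfg$plddt_cutoff)
    # linker absorption: drop tiny included islands
    r <- rle(excluded)
    endpos <- cumsum(r$lengths)
    startpos <- endpos - r$lengths + 1L
    for (k in seq_along(r$values)) {
        if (!r$values[k] && r$lengths[k] < cfg$segment_size) {
            leftExcluded <- k == 1L || r$values[k - 1L]
            rightExcluded <- k == length(r$values) || r$values[k + 1L]
            if (leftExcluded && rightExcluded)
                excluded[startpos[k]:endpos[k]] <- TRUE
        }
    }
    excluded
}

#' Same-domain probability for one residue pair
#'
#' `plogis(w0 - w_dist * distance/dist_scale - w_pae * pae_sym/pae_scale +
#' w_sup * support)`: monotone decreasing in distance and PAE, increasing
#' in support. Vectorized over the three features.
#'
#' @param distance CA--CA distance(s), Angstrom.
#' @param pae_sym Symmetrized PAE value(s), Angstrom.
#' @param support Co-alignment support in \[0, 1\].
#' @param cfg A [parserConfig()].
#' @return Probability in \[0, 1\].
#' @examples
#' pairProbability(8, 3, 1)  # plogis(1.6) ~ 0.832 under defaults
#' @export
pairProbability <- function(distance, pae_sym, support = 0,
                            cfg = parserConfig()) {
    if (any(distance < 0) || any(pae_sym < 0) || any(pae_sym > 35))
        stop("distance must be >= 0 and pae_sym in [0, 35]")
    stats::plogis(cfg$w0 - cfg$w_dist * distance / cfg$dist_scale -
                  cfg$w_pae * pae_sym / cfg$pae_scale +
                  cfg$w_sup * support)
}

#' Chunk unmasked residues into clustering segments
#'
#' Each maximal run of included residues is tiled left to right into
#' windows of `segment_size` residues; a terminal remainder shorter than
#' `segment_size` is merged into the preceding window (or kept alone when
#' the whole run is shorter than `segment_size`). Segments never span a
#' masked gap.
#'
#' @param mask Logical vector from [disorderMask()] (`TRUE` = excluded).
#' @param segment_size Residues per window.
#' @return List of two-element integer vectors `c(start, end)`.
#' @export
buildSegments <- function(mask, segment_size = 5L) {
    segment_size <- as.integer(segment_size)
    segs <- list()
    r <- rle(!mask)
    endpos <- cumsum(r$lengths)
    startpos <- endpos - r$lengths + 1L
    for (k in seq_along(r$values)) {
        if (!r$values[k])
            next
        a <- startpos[k]; b <- endpos[k]; len <- b - a + 1L
        if (len < segment_size) {
            segs[[length(segs) + 1L]] <- c(a, b)
            next
        }
        nwin <- len %/% segment_size
        for (j in seq_len(nwin)) {
            s <- a + (j - 1L) * segment_size
            e <- if (j == nwin) b else s + segment_size - 1L
            segs[[length(segs) + 1L]] <- c(s, e)
        }
    }
    segs
}

#' Average same-domain probability between two segments
#'
#' @param a,b Two-element integer vectors `c(start, end)` (or
#'   single-interval [SegmentList-class] objects).
#' @param prob Residue-pair probability matrix.
#' @return Arithmetic mean of the probabilities over the residue cross
#'   product of `a` and `b`; symmetric in its arguments.
#' @export
segmentLinkage <- function(a, b, prob) {
    toIdx <- function(x) {
        if (is(x, "SegmentList")) residueSet(x) else seq.int(x[1L], x[2L])
    }
    mean(prob[toIdx(a), toIdx(b), drop = FALSE])
}

#' Cluster segments into domains by average linkage
#'
#' Agglomerative merging: repeatedly merge the cluster pair with the
#' highest average linkage (mean pair probability over the residue cross
#' product) while that linkage is at least `linkage_cutoff`. Ties are
#' broken deterministically in favor of the pair whose leftmost residue is
#' smallest (then the smaller partner's leftmost residue). Afterwards,
#' clusters smaller than `min_domain_size` residues are attached to their
#' highest-linkage neighbor when that linkage reaches `linkage_cutoff / 2`,
#' and are otherwise dropped as linker.
#'
#' @param segments List of `c(start, end)` segments from [buildSegments()].
#' @param prob Residue-pair probability matrix.
#' @param cfg A [parserConfig()].
#' @return List of [ParsedDomain-class], ordered by first residue.
#' @export
clusterSegments <- function(segments, prob, cfg = parserConfig()) {
    if (length(segments) == 0L)
        return(list())
    nseg <- length(segments)
    idx <- lapply(segments, function(s) seq.int(s[1L], s[2L]))
    sizes <- lengths(idx)
    # segment-level probability sums; cluster sums are additive under merge
    S <- matrix(0, nseg, nseg)
    for (i in seq_len(nseg))
        for (j in i:nseg)
            S[i, j] <- S[j, i] <- sum(prob[idx[[i]], idx[[j]], drop = FALSE])
    members <- as.list(seq_len(nseg))
    alive <- rep(TRUE, nseg)
    cnt <- sizes
    leftmost <- vapply(segments, `[`, integer(1), 1L)

    linkageMatrix <- function() {
        L <- S / outer(cnt, cnt)
        diag(L) <- -Inf
        L[!alive, ] <- -Inf
        L[, !alive] <- -Inf
        L
    }
    mergeInto <- function(i, j) {
        # fold cluster j into cluster i
        S[i, ] <<- S[i, ] + S[j, ]
        S[, i] <<- S[, i] + S[, j]
        cnt[i] <<- cnt[i] + cnt[j]
        members[[i]] <<- c(members[[i]], members[[j]])
        leftmost[i] <<- min(leftmost[i], leftmost[j])
        alive[j] <<- FALSE
    }
    repeat {
        L <- linkageMatrix()
        best <- max(L)
        if (!is.finite(best) || best < cfg$linkage_cutoff)
            break
        cand <- which(L >= best - 1e-12, arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        lm <- pmin(leftmost[cand[, 1L]], leftmost[cand[, 2L]])
        lm2 <- pmax(leftmost[cand[, 1L]], leftmost[cand[, 2L]])
        pick <- order(lm, lm2)[1L]
        mergeInto(cand[pick, 1L], cand[pick, 2L])
    }
    # resolve undersized clusters, smallest leftmost first
    repeat {
        small <- which(alive & cnt < cfg$min_domain_size)
        if (length(small) == 0L)
            break
        i <- small[order(leftmost[small])][1L]
        L <- linkageMatrix()
        others <- which(alive & seq_along(alive) != i)
        if (length(others) && max(L[i, others]) >= cfg$linkage_cutoff / 2) {
            j <- others[which.max(L[i, others])]
            mergeInto(j, i)
        } else {
            alive[i] <- FALSE   # dropped as linker
        }
    }
    out <- lapply(which(alive), function(i) {
        segs <- segments[members[[i]]]
        sl <- SegmentList(vapply(segs, `[`, integer(1), 1L),
                          vapply(segs, `[`, integer(1), 2L))
        res <- residueSet(sl)
        m <- length(res)
        internal <- if (m > 1L)
            (sum(prob[res, res]) - sum(diag(prob)[res])) / (m^2 - m)
        else 1
        new("ParsedDomain", ranges = sl,
            meanInternalProb = min(max(internal, 0), 1))
    })
    first <- vapply(out, function(d) segmentBounds(domainRanges(d))[1L, 1L],
                    integer(1))
    out[order(first)]
}

#' Parse a protein model into domains
#'
#' Deterministic composition of the parsing stages: symmetrize the PAE,
#' mask disordered/linker residues, compute residue-pair same-domain
#' probabilities from distance, PAE and co-alignment support, chunk the
#' unmasked residues into segments, and cluster the segments into
#' (possibly discontinuous) domains.
#'
#' @param model A [ProteinModel-class].
#' @param support Optional length x length co-alignment support matrix in
#'   \[0, 1\] (e.g. from [genSupport()]); `NULL` means no homology evidence
#'   (all zeros).
#' @param cfg A [parserConfig()].
#' @return List of [ParsedDomain-class], ordered by first residue; empty
#'   when every residue is masked.
#' @export
parseProtein <- function(model, support = NULL, cfg = parserConfig()) {
    stopifnot(is(model, "ProteinModel"))
    n <- proteinLength(model)
    if (is.null(support)) {
        support <- matrix(0, n, n)
    } else {
        support <- as.matrix(support)
        if (nrow(support) != n || ncol(support) != n)
            stop("support matrix dimension does not match protein length")
    }
    paeS <- symmetrizePae(paeMatrix(model))
    mask <- disorderMask(model, cfg)
    if (all(mask))
        return(list())
    d <- as.matrix(stats::dist(caCoords(model)))
    prob <- pairProbability(d, paeS, support, cfg)
    segs <- buildSegments(mask, cfg$segment_size)
    clusterSegments(segs, prob, cfg)
}

#' Convert parsed domains to annotations
#'
#' @param parsed List of [ParsedDomain-class] from [parseProtein()].
#' @param proteinId Protein identifier for the annotations.
#' @return List of [DomainAnnotation-class] with source `"dpam"` and
#'   domain ids `D01`, `D02`, ... in N-to-C order.
#' @export
parsedToAnnotations <- function(parsed, proteinId) {
    lapply(seq_along(parsed), function(i)
        DomainAnnotation(proteinId, sprintf("D%02d", i),
                         domainRanges(parsed[[i]]), "dpam"))
}
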