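#' Generator parameters for synthetic multi-domain proteins
#'
#' The generator emulates the features the parser consumes: compact
#' per-domain CA clouds, block-structured PAE (low within domains, high
#' between them, disorder-level on tails/linkers), Bernoulli co-alignment
#' support, and per-residue pLDDT/SSE annotation. Defaults describe a
#' typical two-domain protein with clear PAE contrast.
#'
#' @param n_domains Number of ground-truth domains.
#' @param domain_length `c(min, max)` residues per domain.
#' @param linker_length `c(min, max)` residues between consecutive domains.
#' @param tail_disorder `c(min, max)` disordered residues at each terminus.
#' @param pae_intra `c(mean, sd)` of within-domain PAE (Angstrom).
#' @param pae_inter `c(mean, sd)` of between-domain PAE (Angstrom).
#' @param pae_disorder_mean Mean PAE on disordered rows/columns (Angstrom).
#' @param support_intra,support_inter Bernoulli probabilities of
#'   co-alignment support within/between domains.
#' @param center_spacing Distance between consecutive domain centers
#'   (Angstrom).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A named list of class `GeneratorParams`.
#' @export
generatorParams <- function(n_domains = 2,
                            domain_length = c(60, 150),
                            linker_length = c(5, 15),
                            tail_disorder = c(5, 25),
                            pae_intra = c(4, 1),
                            pae_inter = c(25, 2),
                            pae_disorder_mean = 28,
                            support_intra = 0.9,
                            support_inter = 0.05,
                            center_spacing = 40,
                            seed = 1L) {
    p <- list(n_domains = as.integer(n_domains),
              domain_length = as.integer(domain_length),
              linker_length = as.integer(linker_length),
              tail_disorder = as.integer(tail_disorder),
              pae_intra = as.numeric(pae_intra),
              pae_inter = as.numeric(pae_inter),
              pae_disorder_mean = as.numeric(pae_disorder_mean),
              support_intra = as.numeric(support_intra),
              support_inter = as.numeric(support_inter),
              center_spacing = as.numeric(center_spacing),
              seed = as.integer(seed))
    if (p$n_domains < 1L)
        stop("n_domains must be >= 1")
    if (any(c(p$domain_length, p$linker_length, p$tail_disorder) < 0))
        stop("all length bounds must be >= 0")
    if (p$domain_length[1L] < 1L)
        stop("domains must contain at least one residue")
    if (p$pae_intra[1L] >= p$pae_inter[1L])
        stop("pae_intra mean must be below pae_inter mean")
    if (p$support_intra <= p$support_inter)
        stop("support_intra must exceed support_inter")
    if (any(c(p$support_intra, p$support_inter) < 0) ||
        any(c(p$support_intra, p$support_inter) > 1))
        stop("support probabilities must lie in [0, 1]")
    structure(p, class = c("GeneratorParams", "list"))
}

#' GroundTruth: one synthetic protein with known segmentation
#'
#' @slot protein The [ProteinModel-class] (coordinates, PAE, pLDDT, SSE).
#' @slot domains List of [DomainAnnotation-class] with source `"truth"`.
#' @slot disordered A [SegmentList-class] of tail/linker residues, or
#'   `NULL` when the chain is fully ordered.
#' @export
setClass("GroundTruth", representation(
    protein = "ProteinModel",
    domains = "list",
    disordered = "ANY"))

setValidity("GroundTruth", function(object) {
    if (!all(vapply(object@domains, is, logical(1), "DomainAnnotation")))
        return("domains must be DomainAnnotation objects")
    if (!all(vapply(object@domains, domainSource, character(1)) == "truth"))
        return("ground-truth domains must carry source 'truth'")
    n <- proteinLength(object@protein)
    all_res <- unlist(lapply(object@domains,
                             function(d) residueSet(domainRanges(d))))
    if (!is.null(object@disordered)) {
        if (!is(object@disordered, "SegmentList"))
            return("disordered must be a SegmentList or NULL")
        all_res <- c(all_res, residueSet(object@disordered))
    }
    if (anyDuplicated(all_res))
        return("domain and disordered ranges must be pairwise disjoint")
    if (length(all_res) && max(all_res) > n)
        return("ranges exceed protein length")
    TRUE
})

#' @describeIn GroundTruth Display a GroundTruth.
#' @param object A GroundTruth.
#' @export
setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth %s: %d residues, %d domain(s), %d disordered\n",
                proteinId(object@protein), proteinLength(object@protein),
                length(object@domains),
                if (is.null(object@disordered)) 0L
                else totalLength(object@disordered)))
})

#' @rdname accessors
#' @export
setGeneric("truthProtein", function(x) standardGeneric("truthProtein"))
#' @rdname accessors
#' @export
setMethod("truthProtein", "GroundTruth", function(x) x@protein)
#' @rdname accessors
#' @export
setGeneric("truthDomains", function(x) standardGeneric("truthDomains"))
#' @rdname accessors
#' @export
setMethod("truthDomains", "GroundTruth", function(x) x@domains)
#' @rdname accessors
#' @export
setGeneric("disorderedRanges", function(x) standardGeneric("disorderedRanges"))
#' @rdname accessors
#' @export
setMethod("disorderedRanges", "GroundTruth", function(x) x@disordered)

# residue -> domain membership vector: 0 = disordered/linker, k = domain k
.membership <- function(domains, disordered, n) {
    m <- integer(n)
    for (k in seq_along(domains))
        m[residueSet(domainRanges(domains[[k]]))] <- k
    m
}

.sampleLen <- function(bounds) {
    if (bounds[1L] >= bounds[2L]) bounds[1L]
    else sample(bounds[1L]:bounds[2L], 1L)
}

# confined random walk: CA steps of 3.8 A kept within `radius` of `center`
.domainWalk <- function(len, center, radius, start = NULL) {
    pos <- matrix(0, len, 3)
    cur <- if (is.null(start)) center + stats::rnorm(3, 0, radius / 3)
           else start
    for (i in seq_len(len)) {
        step <- stats::rnorm(3)
        step <- 3.8 * step / sqrt(sum(step^2))
        nxt <- cur + step
        if (sqrt(sum((nxt - center)^2)) > radius) {
            pull <- center - cur + stats::rnorm(3, 0, 1)
            nxt <- cur + 3.8 * pull / sqrt(sum(pull^2))
        }
        pos[i, ] <- nxt
        cur <- nxt
    }
    pos
}

# alternating helix/strand runs with coil spacers, truncated to `len`
.domainSse <- function(len) {
    unit <- c(rep("H", 9), rep("C", 3), rep("E", 5), rep("C", 3))
    rep(unit, length.out = len)
}

#' Generate one ground-truth protein
#'
#' Lays out `n_domains` compact CA clouds (confined 3.8-Angstrom random
#' walks around centers spaced `center_spacing` apart) joined by linkers
#' and flanked by disordered tails, then attaches a block-structured PAE
#' matrix ([genPae()]), pLDDT (high in domains, low in disorder) and
#' per-domain alternating helix/strand SSE labels. Deterministic for a
#' fixed `params$seed`.
#'
#' @param params A [generatorParams()].
#' @param proteinId Identifier for the protein.
#' @return A [GroundTruth-class].
#' @export
genProtein <- function(params = generatorParams(), proteinId = "SYN0001") {
    stopifnot(inherits(params, "GeneratorParams"))
    set.seed(params$seed)
    nd <- params$n_domains
    dlen <- vapply(seq_len(nd), function(i) .sampleLen(params$domain_length),
                   integer(1))
    llen <- if (nd > 1L)
        vapply(seq_len(nd - 1L), function(i) .sampleLen(params$linker_length),
               integer(1))
    else integer(0)
    ntail <- .sampleLen(params$tail_disorder)
    ctail <- .sampleLen(params$tail_disorder)
    n <- ntail + sum(dlen) + sum(llen) + ctail
    if (n < 1L)
        stop("infeasible geometry: total length is 0")

    # residue layout
    pos <- ntail
    dstart <- integer(nd); dend <- integer(nd)
    for (k in seq_len(nd)) {
        dstart[k] <- pos + 1L
        dend[k] <- pos + dlen[k]
        pos <- dend[k] + if (k < nd) llen[k] else 0L
    }
    domains <- lapply(seq_len(nd), function(k)
        DomainAnnotation(proteinId, sprintf("T%02d", k),
                         SegmentList(dstart[k], dend[k]), "truth"))
    dis <- integer(0)
    if (ntail > 0L) dis <- c(dis, seq_len(ntail))
    if (nd > 1L)
        for (k in seq_len(nd - 1L))
            if (llen[k] > 0L) dis <- c(dis, (dend[k] + 1L):(dstart[k + 1L] - 1L))
    if (ctail > 0L) dis <- c(dis, (n - ctail + 1L):n)
    disordered <- if (length(dis)) segmentsFromResidues(dis) else NULL

    # coordinates: compact domain clouds on a line of centers, floppy rest
    centers <- lapply(seq_len(nd), function(k)
        c((k - 1) * params$center_spacing, 0, 0) + stats::rnorm(3, 0, 2))
    coords <- matrix(NA_real_, n, 3)
    for (k in seq_len(nd)) {
        radius <- 2.3 * dlen[k]^0.38   # globular-size scaling
        coords[dstart[k]:dend[k], ] <- .domainWalk(dlen[k], centers[[k]],
                                                   radius)
    }
    walkFrom <- function(from, len) {
        out <- matrix(0, len, 3)
        cur <- from
        for (i in seq_len(len)) {
            step <- stats::rnorm(3)
            cur <- cur + 3.8 * step / sqrt(sum(step^2))
            out[i, ] <- cur
        }
        out
    }
    if (ntail > 0L)
        coords[ntail:1, ] <- walkFrom(coords[ntail + 1L, ], ntail)
    if (ctail > 0L)
        coords[(n - ctail + 1L):n, ] <- walkFrom(coords[n - ctail, ], ctail)
    if (nd > 1L)
        for (k in seq_len(nd - 1L))
            if (llen[k] > 0L) {
                a <- dend[k]; b <- dstart[k + 1L]
                frac <- seq_len(llen[k]) / (llen[k] + 1L)
                coords[(a + 1L):(b - 1L), ] <-
                    (1 - frac) %o% coords[a, ] + frac %o% coords[b, ] +
                    matrix(stats::rnorm(3 * llen[k], 0, 1.5), llen[k], 3)
            }

    memb <- integer(n)
    for (k in seq_len(nd)) memb[dstart[k]:dend[k]] <- k
    pae <- .paeFromMembership(memb, params)
    plddt <- ifelse(memb > 0L, stats::runif(n, 85, 98), stats::runif(n, 25, 45))
    sse <- rep("C", n)
    for (k in seq_len(nd)) sse[dstart[k]:dend[k]] <- .domainSse(dlen[k])

    protein <- ProteinModel(proteinId, coords, pae, plddt = plddt, sse = sse)
    new("GroundTruth", protein = protein, domains = domains,
        disordered = disordered)
}

.paeFromMembership <- function(memb, params) {
    n <- length(memb)
    same <- outer(memb, memb, "==") & memb > 0L
    disA <- matrix(memb == 0L, n, n) | matrix(memb == 0L, n, n, byrow = TRUE)
    pae <- matrix(stats::rnorm(n * n, params$pae_inter[1L],
                               params$pae_inter[2L]), n, n)
    pae[same] <- stats::rnorm(sum(same), params$pae_intra[1L],
                              params$pae_intra[2L])
    pae[disA] <- stats::rnorm(sum(disA), params$pae_disorder_mean, 2)
    pae <- pmin(pmax(pae, 0.2), 31.75)
    diag(pae) <- 0.2
    pae
}

#' Regenerate a PAE matrix for a ground truth
#'
#' Entry `(i, j)` is drawn from the intra distribution when `i` and `j`
#' share a truth domain, from the inter distribution when they belong to
#' different domains, and around `pae_disorder_mean` when either residue
#' is disordered. Values are clipped to \[0.2, 31.75\] (the AFDB encoding
#' ceiling); the matrix is not symmetrized (downstream code symmetrizes).
#'
#' @param truth A [GroundTruth-class].
#' @param params A [generatorParams()].
#' @return A square numeric matrix.
#' @export
genPae <- function(truth, params = generatorParams()) {
    stopifnot(is(truth, "GroundTruth"))
    n <- proteinLength(truthProtein(truth))
    memb <- .membership(truthDomains(truth), disorderedRanges(truth), n)
    .paeFromMembership(memb, params)
}

#' Generate a co-alignment support matrix
#'
#' Emulates homology-search evidence: entry `(i, j)` is 1 when the pair
#' was (synthetically) co-aligned to one reference domain. Draws are
#' Bernoulli at `support_intra` within truth domains and `support_inter`
#' elsewhere; rows/columns of disordered residues are zero. The matrix is
#' symmetric with unit diagonal on ordered residues.
#'
#' @param truth A [GroundTruth-class].
#' @param params A [generatorParams()].
#' @return A square 0/1 matrix.
#' @export
genSupport <- function(truth, params = generatorParams()) {
    stopifnot(is(truth, "GroundTruth"))
    n <- proteinLength(truthProtein(truth))
    memb <- .membership(truthDomains(truth), disorderedRanges(truth), n)
    same <- outer(memb, memb, "==") & memb > 0L
    p <- ifelse(same, params$support_intra, params$support_inter)
    s <- matrix(0, n, n)
    up <- upper.tri(s)
    s[up] <- stats::rbinom(sum(up), 1L, p[up])
    s <- s + t(s)
    diag(s) <- 1
    dis <- memb == 0L
    s[dis, ] <- 0
    s[, dis] <- 0
    s
}

#' Perturb a ground-truth segmentation
#'
#' Produces an alternative (`source = "ted"`) segmentation emulating the
#' disagreement modes seen between independent domain definitions:
#'
#' * `split_at`: one domain is cut at a residue position into two
#'   contiguous halves (residues before the position, and from it on).
#' * `merge`: two domains are replaced by the union of their ranges.
#' * `trim_termini`: `k` residues are removed from each terminus of a
#'   domain.
#' * `carve_insertion`: an interior region is carved out of a domain as
#'   its own annotation (an insert presented as an independent domain),
#'   leaving the remainder as a second annotation.
#'
#' Untouched domains are copied through. Resulting annotations are
#' renumbered `TED01`, `TED02`, ... in N-to-C order.
#'
#' @param domains List of [DomainAnnotation-class] (the parent chopping).
#' @param spec A list with element `op` (one of `"split_at"`, `"merge"`,
#'   `"trim_termini"`, `"carve_insertion"`) and its arguments: `domain`
#'   (index of the target domain), `position` (split residue), `i`/`j`
#'   (merge partners), `k` (trim width), `carve` (a [SegmentList-class]).
#' @return List of [DomainAnnotation-class] with source `"ted"`.
#' @export
perturbAnnotation <- function(domains, spec) {
    stopifnot(length(domains) >= 1L,
              all(vapply(domains, is, logical(1), "DomainAnnotation")))
    pid <- proteinId(domains[[1L]])
    rangesOf <- function(i) domainRanges(domains[[i]])
    keep <- seq_along(domains)
    pieces <- list()
    op <- spec$op
    if (op == "split_at") {
        i <- spec$domain
        res <- residueSet(rangesOf(i))
        pos <- spec$position
        lo <- res[res < pos]; hi <- res[res >= pos]
        if (length(lo) == 0L || length(hi) == 0L)
            stop("split position ", pos, " does not bisect domain ", i)
        pieces <- list(segmentsFromResidues(lo), segmentsFromResidues(hi))
        keep <- setdiff(keep, i)
    } else if (op == "merge") {
        i <- spec$i; j <- spec$j
        if (i == j || i > length(domains) || j > length(domains))
            stop("merge requires two distinct existing domains")
        pieces <- list(segmentUnion(rangesOf(i), rangesOf(j)))
        keep <- setdiff(keep, c(i, j))
    } else if (op == "trim_termini") {
        i <- spec$domain
        res <- residueSet(rangesOf(i))
        k <- spec$k
        if (length(res) <= 2L * k)
            stop("trim width ", k, " leaves no residues in domain ", i)
        pieces <- list(segmentsFromResidues(res[(k + 1L):(length(res) - k)]))
        keep <- setdiff(keep, i)
    } else if (op == "carve_insertion") {
        i <- spec$domain
        carve <- segmentIntersection(spec$carve, rangesOf(i))
        if (is.null(carve))
            stop("carve range lies outside domain ", i)
        remainder <- segmentDifference(rangesOf(i), carve)
        if (is.null(remainder))
            stop("carve range covers all of domain ", i)
        pieces <- list(carve, remainder)
        keep <- setdiff(keep, i)
    } else {
        stop("unknown perturbation op '", op, "'")
    }
    out <- c(lapply(keep, rangesOf), pieces)
    first <- vapply(out, function(sl) segmentBounds(sl)[1L, 1L], integer(1))
    out <- out[order(first)]
    lapply(seq_along(out), function(k)
        DomainAnnotation(pid, sprintf("TED%02d", k), out[[k]], "ted"))
}

#' ECOD-style architecture catalog
#'
#' The 18 architecture names used for mock metadata, spanning all-alpha,
#' all-beta, mixed and low-complexity arrangements.
#'
#' @return Character vector of 18 architecture names.
#' @export
ecodArchitectures <- function() {
    c("a/b three-layered sandwiches", "alpha arrays", "a+b two layers",
      "beta barrels", "beta sandwiches", "alpha superhelices",
      "a+b complex topology", "mixed a+b and a/b", "a/b barrels",
      "beta duplicates or obligate multimers", "alpha bundles",
      "a+b four layers", "alpha complex topology", "beta meanders",
      "beta complex topology", "few secondary structure elements",
      "extended segments", "a+b duplicates or obligate multimers")
}

.xGroupCatalog <- c(
    "P-loop domain-like", "Rossmann-like", "TIM beta/alpha-barrel",
    "Protein kinase/SAICAR synthase/ATP-grasp", "Cysteine proteinases-like",
    "Zincin-like", "Ribonuclease H-like", "Repetitive alpha hairpins",
    "Single-stranded right-handed beta-helix", "beta-propeller-like",
    "SH3", "HTH", "Immunoglobulin-like beta-sandwich", "Rubredoxin-like",
    "OB-fold", "Pili subunits", "RING/U-box-like",
    "His-Me finger endonucleases", "Outer membrane meander beta-barrels")

#' Generate mock assignment metadata for a set of domains
#'
#' Marginal distributions emulate a realistic assignment landscape:
#' reference-assignment confidence is a two-component mixture (a high
#' component near 0.97 and a diffuse component near 0.5), Best_Seq_Rel is
#' bimodal on \[0, 1\] (clear sequence hits near 1 against a low tail),
#' the structural Z-score is gamma with configurable mean and standard
#' deviation, architecture/X-group labels are drawn from packaged
#' catalogs, reference lengths are log-normal multiples of the domain
#' length, and transmembrane-segment counts are Poisson with a small mean.
#'
#' @param annotations List of [DomainAnnotation-class].
#' @param seed Integer seed.
#' @param daliMean,daliSd Target mean and standard deviation of the
#'   gamma-distributed structural Z-score.
#' @param pHighConfidence Mixture weight of the high-confidence component.
#' @param tmRate Poisson mean of the transmembrane-segment count.
#' @return A data frame with columns `protein_id`, `domain_id`,
#'   `confidence`, `best_seq_rel`, `dali_z`, `architecture`, `x_group`,
#'   `reference_length`, `n_tm`.
#' @export
genMetadata <- function(annotations, seed = 1L, daliMean = 9.18,
                        daliSd = 6.99, pHighConfidence = 0.35,
                        tmRate = 0.05) {
    stopifnot(all(vapply(annotations, is, logical(1), "DomainAnnotation")))
    set.seed(seed)
    n <- length(annotations)
    lens <- vapply(annotations, totalLength, integer(1))
    high <- stats::rbinom(n, 1L, pHighConfidence) == 1L
    confidence <- ifelse(high, 0.9 + 0.1 * stats::rbeta(n, 5, 1.5),
                         0.9 * stats::rbeta(n, 5, 5))
    seqHigh <- stats::rbinom(n, 1L, 0.55) == 1L
    best_seq_rel <- ifelse(seqHigh, stats::rbeta(n, 25, 1),
                           stats::rbeta(n, 1.2, 5))
    shape <- (daliMean / daliSd)^2
    dali_z <- stats::rgamma(n, shape = shape, rate = shape / daliMean)
    archs <- ecodArchitectures()
    archWeights <- rev(seq_along(archs))^1.5
    architecture <- sample(archs, n, replace = TRUE, prob = archWeights)
    x_group <- sample(.xGroupCatalog, n, replace = TRUE)
    reference_length <- pmax(10L, as.integer(round(
        lens * stats::rlnorm(n, meanlog = 0.15, sdlog = 0.45))))
    data.frame(
        protein_id = vapply(annotations, proteinId, character(1)),
        domain_id = vapply(annotations, domainId, character(1)),
        confidence = round(confidence, 4),
        best_seq_rel = round(best_seq_rel, 4),
        dali_z = round(dali_z, 2),
        architecture = architecture,
        x_group = x_group,
        reference_length = reference_length,
        n_tm = stats::rpois(n, tmRate),
        stringsAsFactors = FALSE)
}

# derive a per-protein substream seed below 2^31 from a master seed
.deriveSeed <- function(seed, i) {
    as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Write generator parameters to a flat key=value file
#'
#' @param params A [generatorParams()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGeneratorConfig <- function(params, path) {
    lines <- vapply(names(params), function(k)
        paste0(k, "=", paste(params[[k]], collapse = ",")), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read generator parameters from a flat key=value file
#'
#' @param path Path written by [writeGeneratorConfig()].
#' @return A [generatorParams()].
#' @export
readGeneratorConfig <- function(path) {
    lines <- readLines(path)
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- lapply(kv, function(x)
        as.numeric(strsplit(x[2L], ",", fixed = TRUE)[[1L]]))
    names(vals) <- vapply(kv, `[`, character(1), 1L)
    do.call(generatorParams, vals)
}

# deterministically allocate perturbation modes: every requested mode at
# least once, remainder by weight, order shuffled under the current RNG
.allocateModes <- function(mix, n) {
    mix <- mix[mix > 0]
    modes <- names(mix)
    if (n < length(modes))
        modes <- modes[seq_len(n)]
    extra <- n - length(modes)
    if (extra > 0L) {
        w <- mix / sum(mix)
        counts <- diff(round(cumsum(w) * extra))
        counts <- c(round(w[1L] * extra), counts)
        modes <- c(modes, rep(names(mix), counts))
    }
    sample(modes, n)
}

#' Generate a complete synthetic cohort fixture
#'
#' For each protein: a ground truth ([genProtein()]) under a per-protein
#' substream seed, a support matrix, and a perturbed alternative
#' segmentation (one perturbation mode per protein, allocated so that
#' every requested mode is represented). Writes a fixture directory --
#' one PDB and one PAE JSON per protein, one chopping TSV (truth + ted
#' rows) and one metadata TSV per cohort, plus the generator config --
#' and returns the in-memory objects.
#'
#' @param nProteins Number of proteins.
#' @param params A [generatorParams()]; its `seed` is the cohort master
#'   seed.
#' @param perturbMix Named weights over `carve`, `split`, `merge`, `trim`.
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @return A list with elements `truths`, `supports`, `tedAnnotations`
#'   (per protein) plus `metadata` (data frame for the ted side), `modes`
#'   and `dir`.
#' @export
genCohort <- function(nProteins, params = generatorParams(),
                      perturbMix = c(carve = 0.25, split = 0.25,
                                     merge = 0.25, trim = 0.25),
                      dir = NULL) {
    stopifnot(nProteins >= 1L)
    set.seed(params$seed)
    modes <- .allocateModes(perturbMix, nProteins)
    ids <- sprintf("SYN%04d", seq_len(nProteins))
    truths <- vector("list", nProteins)
    supports <- vector("list", nProteins)
    teds <- vector("list", nProteins)
    for (i in seq_len(nProteins)) {
        pi_params <- params
        pi_params$seed <- .deriveSeed(params$seed, i)
        truths[[i]] <- genProtein(pi_params, proteinId = ids[i])
        set.seed(.deriveSeed(params$seed, i) %% 2000000011L)
        supports[[i]] <- genSupport(truths[[i]], params)
        teds[[i]] <- .applyMode(truths[[i]], modes[i])
    }
    metadata <- genMetadata(unlist(teds), seed = .deriveSeed(params$seed, 0L))
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_len(nProteins)) {
            prot <- truthProtein(truths[[i]])
            writeCaPdb(caCoords(prot), file.path(dir, paste0(ids[i], ".pdb")),
                       plddt = plddtScores(prot))
            writePaeJson(paeMatrix(prot),
                         file.path(dir, paste0(ids[i], "_pae.json")))
        }
        writeChoppingTable(c(unlist(lapply(truths, truthDomains)),
                             unlist(teds)),
                           file.path(dir, "chopping.tsv"))
        writeReportTsv(metadata, file.path(dir, "metadata.tsv"))
        writeGeneratorConfig(params, file.path(dir, "config.txt"))
    }
    list(truths = truths, supports = supports, tedAnnotations = teds,
         metadata = metadata, modes = modes, dir = dir)
}

# apply one named perturbation mode to a ground truth (RNG already seeded)
.applyMode <- function(truth, mode) {
    doms <- truthDomains(truth)
    nd <- length(doms)
    if (mode == "merge" && nd < 2L)
        mode <- "trim"
    spec <- switch(mode,
        carve = {
            lens <- vapply(doms, totalLength, integer(1))
            i <- which.max(lens)
            res <- residueSet(domainRanges(doms[[i]]))
            m <- length(res)
            w <- max(10L, as.integer(round(0.35 * m)))
            s <- sample(seq.int(5L, m - w - 4L), 1L)
            list(op = "carve_insertion", domain = i,
                 carve = segmentsFromResidues(res[s:(s + w - 1L)]))
        },
        split = {
            lens <- vapply(doms, totalLength, integer(1))
            i <- which.max(lens)
            res <- residueSet(domainRanges(doms[[i]]))
            list(op = "split_at", domain = i,
                 position = res[as.integer(length(res) / 2)])
        },
        merge = list(op = "merge", i = 1L, j = 2L),
        trim = {
            i <- sample(nd, 1L)
            kmax <- max(1L, (totalLength(domainRanges(doms[[i]])) - 5L) %/% 2L)
            list(op = "trim_termini", domain = i, k = min(8L, kmax))
        },
        stop("unknown perturbation mode '", mode, "'"))
    perturbAnnotation(doms, spec)
}
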