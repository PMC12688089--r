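test_that("PAE symmetrization averages the two directions", {
    expect_equal(symmetrizePae(matrix(c(0, 4, 2, 0), 2, byrow = TRUE)),
                 matrix(c(0, 3, 3, 0), 2))
    m <- matrix(c(0, 5, 5, 0), 2)
    expect_equal(symmetrizePae(m), m)  # symmetric input unchanged
    set.seed(1)
    for (i in 1:20) {
        m <- matrix(runif(49, 0, 30), 7)
        s <- symmetrizePae(m)
        expect_identical(s, t(s))
    }
    expect_error(symmetrizePae(matrix(0, 2, 3)), "square")
})

test_that("disorder mask excludes disordered tails, not domain cores", {
    # uniform low PAE: nothing excluded
    expect_false(any(disorderMask(toyModel(30, pae_value = 3))))
    # uniform high PAE: everything excluded, parser returns no domains
    hi <- toyModel(30, pae_value = 30)
    expect_true(all(disorderMask(hi)))
    expect_length(parseProtein(hi), 0L)
    # synthetic protein with disordered tails: exactly the disordered
    # residues are excluded
    tr <- genProtein(generatorParams(seed = 7))
    mask <- disorderMask(truthProtein(tr))
    expect_identical(which(mask), residueSet(disorderedRanges(tr)))
    # low pLDDT also masks, when present
    m <- toyModel(30, pae_value = 3, plddt = c(rep(30, 6), rep(90, 24)))
    expect_identical(which(disorderMask(m)), 1:6)
})

test_that("pair probability follows the stated logistic form", {
    cfg0 <- parserConfig(w0 = 2, w_dist = 0, w_pae = 0, w_sup = 0)
    expect_equal(pairProbability(8, 3, 1, cfg0), plogis(2))
    expect_equal(pairProbability(100, 30, 0, cfg0), plogis(2))
    # defaults: (8 A, 3 A, 1.0) -> logistic(1 - 0.8 - 0.6 + 2)
    expect_equal(pairProbability(8, 3, 1), plogis(1.6), tolerance = 1e-12)
    expect_equal(plogis(1.6), 0.832, tolerance = 1e-3)
    # monotone: more PAE or distance never raises it; support never lowers
    set.seed(2)
    for (i in 1:100) {
        d <- runif(1, 0, 60); p <- runif(1, 0, 30); s <- runif(1)
        base <- pairProbability(d, p, s)
        expect_lte(pairProbability(d, p + runif(1, 0, 5), s), base)
        expect_lte(pairProbability(d + runif(1, 0, 10), p, s), base)
        expect_gte(pairProbability(d, p, min(1, s + runif(1, 0, 0.5))),
                   base)
    }
})

test_that("segments tile unmasked runs with remainder merging", {
    mask <- rep(TRUE, 40)
    mask[1:12] <- FALSE
    expect_equal(buildSegments(mask, 5), list(c(1L, 5L), c(6L, 12L)))
    mask <- rep(TRUE, 10); mask[1:4] <- FALSE
    expect_equal(buildSegments(mask, 5), list(c(1L, 4L)))
    mask <- rep(TRUE, 40); mask[1:10] <- FALSE; mask[21:30] <- FALSE
    segs <- buildSegments(mask, 5)
    expect_length(segs, 4L)
    expect_true(all(vapply(segs, function(s)
        all(!mask[s[1]:s[2]]), logical(1))))  # no segment spans the gap
})

test_that("segment linkage is the mean pair probability, symmetric", {
    n <- 20
    set.seed(3)
    prob <- matrix(runif(n * n), n)
    prob <- (prob + t(prob)) / 2
    a <- c(1L, 5L); b <- c(11L, 15L)
    brute <- mean(vapply(1:5, function(i)
        mean(prob[i, 11:15]), numeric(1)))
    expect_equal(segmentLinkage(a, b, prob), brute)
    expect_equal(segmentLinkage(a, b, prob), segmentLinkage(b, a, prob))
    uni <- matrix(0.7, n, n)
    expect_equal(segmentLinkage(a, b, uni), 0.7)
})

test_that("clustering merges by average linkage with deterministic ties", {
    # all probabilities 1: a single domain covering all segments
    n <- 30
    segs <- buildSegments(rep(FALSE, n), 5)
    one <- clusterSegments(segs, matrix(1, n, n))
    expect_length(one, 1L)
    expect_equal(totalLength(domainRanges(one[[1]])), n)
    # two blocks with ~zero inter-block probability: two domains
    n <- 100
    prob <- matrix(0.001, n, n)
    prob[1:50, 1:50] <- 0.95
    prob[51:100, 51:100] <- 0.95
    two <- clusterSegments(buildSegments(rep(FALSE, n), 5), prob)
    expect_length(two, 2L)
    expect_equal(formatRangeString(domainRanges(two[[1]])), "1-50")
    expect_equal(formatRangeString(domainRanges(two[[2]])), "51-100")
    # clusters below min_domain_size with no neighbor are dropped
    lone <- clusterSegments(buildSegments(rep(FALSE, 10), 5),
                            matrix(0.9, 10, 10),
                            parserConfig(min_domain_size = 25))
    expect_length(lone, 0L)
})

test_that("end-to-end parsing recovers synthetic ground truth", {
    # single-domain fixture: one domain covering all non-tail residues
    params <- generatorParams(n_domains = 1, seed = 5)
    tr <- genProtein(params)
    set.seed(5)
    pd <- parseProtein(truthProtein(tr), genSupport(tr))
    expect_length(pd, 1L)
    expect_equal(segmentBounds(domainRanges(pd[[1]])),
                 segmentBounds(domainRanges(truthDomains(tr)[[1]])))
    # two-domain fixture with support
    tr2 <- genProtein(generatorParams(seed = 7))
    set.seed(7)
    pd2 <- parseProtein(truthProtein(tr2), genSupport(tr2))
    expect_length(pd2, 2L)
    for (k in 1:2)
        expect_equal(segmentBounds(domainRanges(pd2[[k]])),
                     segmentBounds(domainRanges(truthDomains(tr2)[[k]])))
    expect_true(all(vapply(pd2, meanInternalProb, numeric(1)) > 0.5))
})

test_that("parsed domains partition unmasked residues", {
    for (s in c(2, 4, 6)) {
        tr <- genProtein(generatorParams(seed = s))
        set.seed(s)
        pd <- parseProtein(truthProtein(tr), genSupport(tr))
        res <- lapply(pd, function(d) residueSet(domainRanges(d)))
        all_res <- unlist(res)
        expect_false(anyDuplicated(all_res) > 0)     # pairwise disjoint
        mask <- disorderMask(truthProtein(tr))
        expect_true(all(!mask[all_res]))             # only unmasked residues
        # ordered by first residue
        firsts <- vapply(res, min, integer(1))
        expect_false(is.unsorted(firsts))
    }
})

test_that("parsing is invariant under protein relabeling", {
    tr <- genProtein(generatorParams(seed = 13))
    prot <- truthProtein(tr)
    set.seed(13)
    sup <- genSupport(tr)
    relabeled <- ProteinModel("OTHER", caCoords(prot), paeMatrix(prot),
                              plddt = plddtScores(prot),
                              sse = sseLabels(prot))
    a <- parseProtein(prot, sup)
    b <- parseProtein(relabeled, sup)
    expect_equal(lapply(a, function(d) segmentBounds(domainRanges(d))),
                 lapply(b, function(d) segmentBounds(domainRanges(d))))
})
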