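test_that("intersection sizes match the worked discontinuous example", {
    full <- parseRangeString("1-370")
    insert <- parseRangeString("198-234,282-371")
    expect_equal(intersectionSize(full, insert), 126L)
    expect_equal(intersectionSize(full, full), 370L)
    expect_equal(intersectionSize(parseRangeString("1-10"),
                                  parseRangeString("20-30")), 0L)
})

test_that("interval sweep equals brute-force residue sets on random pairs", {
    set.seed(8)
    for (i in 1:200) {
        a <- randomSegmentList()
        b <- randomSegmentList()
        expect_identical(intersectionSize(a, b), bruteIntersection(a, b))
    }
})

test_that("dual fractions come out as printed for the embedded-insert case", {
    f <- overlapFractions(parseRangeString("1-370"),
                          parseRangeString("198-234,282-371"))
    expect_equal(unname(f["intersection"]), 126)
    expect_equal(unname(f["f_dpam"]), 126 / 370)
    expect_equal(unname(f["f_ted"]), 126 / 127)
    a <- DomainAnnotation("P", "D1", "1-100", "dpam")
    expect_equal(unname(overlapFractions(a, a)[c("f_dpam", "f_ted")]),
                 c(1, 1))
    # contained at half length
    b <- DomainAnnotation("P", "T1", "26-75", "ted")
    f2 <- overlapFractions(a, b)
    expect_equal(unname(f2["f_ted"]), 1)
    expect_equal(unname(f2["f_dpam"]), 0.5)
    expect_error(overlapFractions(a, DomainAnnotation("Q", "T1", "1-10",
                                                      "ted")),
                 "one protein")
})

test_that("significance requires either fraction strictly above 0.5", {
    expect_true(isSignificant(0.51, 0.1))
    expect_false(isSignificant(0.5, 0.5))
    expect_true(isSignificant(0.0, 1.0))
})

test_that("overlap categories are exclusive, exhaustive and symmetric", {
    expect_equal(categorizeOverlap(126 / 370, 126 / 127), "ted_embedded")
    expect_equal(categorizeOverlap(0.9, 0.9), "consistent")
    expect_equal(categorizeOverlap(0.8, 0.8), "intermediate")
    grid <- seq(0, 1, by = 0.05)   # includes 0.5/0.6/0.8 boundaries
    for (fd in grid) for (ft in grid) {
        cat <- categorizeOverlap(fd, ft)
        expect_true(cat %in% c("consistent", "ted_embedded",
                               "dpam_embedded", "intermediate"))
        # swapping roles swaps the embedded categories
        swapped <- categorizeOverlap(ft, fd)
        expect_equal(swapped, switch(cat,
            ted_embedded = "dpam_embedded",
            dpam_embedded = "ted_embedded", cat))
    }
})

test_that("pairing matches each ted domain to its best dpam partner", {
    dpam <- list(DomainAnnotation("P", "D01", "1-370", "dpam"))
    ted <- list(DomainAnnotation("P", "TED02", "198-234,282-371", "ted"))
    pairs <- pairDomains(dpam, ted)
    expect_equal(nrow(pairs), 1L)
    expect_equal(pairs$category, "ted_embedded")
    expect_equal(pairs$intersection, 126L)

    # a ted domain covering two dpam domains equally pairs with the earlier
    dpam2 <- list(DomainAnnotation("P", "D01", "1-100", "dpam"),
                  DomainAnnotation("P", "D02", "101-200", "dpam"))
    ted2 <- list(DomainAnnotation("P", "T1", "1-200", "ted"))
    pairs2 <- pairDomains(dpam2, ted2)
    expect_equal(pairs2$dpam_id, "D01")
    expect_equal(pairs2$f_ted, 0.5)
    expect_equal(pairs2$f_dpam, 1)

    # no overlap anywhere: empty
    expect_equal(nrow(pairDomains(
        list(DomainAnnotation("P", "D01", "1-50", "dpam")),
        list(DomainAnnotation("P", "T1", "100-150", "ted")))), 0L)

    # containment law: ted inside dpam has f_ted = 1
    inner <- pairDomains(list(DomainAnnotation("P", "D01", "1-200", "dpam")),
                         list(DomainAnnotation("P", "T1", "50-120", "ted")))
    expect_equal(inner$f_ted, 1)

    # boundary fractions are classified exactly: 80/100 is not > 0.8
    edge <- pairDomains(list(DomainAnnotation("P", "D01", "1-100", "dpam")),
                        list(DomainAnnotation("P", "T1", "1-80", "ted")))
    expect_equal(edge$f_dpam, 0.8)
    expect_equal(edge$category, "intermediate")
})

test_that("cohort comparison is deterministic and skips one-sided proteins", {
    dpam <- list(DomainAnnotation("A", "D01", "1-100", "dpam"),
                 DomainAnnotation("B", "D01", "1-100", "dpam"))
    ted <- list(DomainAnnotation("B", "T1", "1-100", "ted"),
                DomainAnnotation("C", "T1", "1-100", "ted"))
    expect_message(pairs <- compareCohort(dpam, ted), "A.*C|C.*A")
    expect_equal(pairs$protein_id, "B")
    expect_equal(pairs$category, "consistent")
})

test_that("cohort-level categories reflect the perturbation geometry", {
    # identity cohort: all consistent
    truth <- lapply(1:3, function(i)
        DomainAnnotation(sprintf("P%d", i), "D01", "1-100", "dpam"))
    ted <- lapply(1:3, function(i)
        DomainAnnotation(sprintf("P%d", i), "T01", "1-100", "ted"))
    expect_true(all(compareCohort(truth, ted)$category == "consistent"))

    # carved cohort: every carved insert is ted_embedded in its parent
    for (s in 1:5) {
        tr <- genProtein(generatorParams(seed = 400 + s))
        doms <- truthDomains(tr)
        asDpam <- lapply(doms, function(d)
            DomainAnnotation(proteinId(d), domainId(d), domainRanges(d),
                             "dpam"))
        res <- residueSet(domainRanges(doms[[1]]))
        w <- length(res) %/% 3
        ted <- perturbAnnotation(doms, list(
            op = "carve_insertion", domain = 1,
            carve = segmentsFromResidues(res[(w + 1):(2 * w)])))
        pairs <- pairDomains(asDpam, ted)
        carvedRow <- pairs[pairs$intersection == w, ]
        expect_equal(carvedRow$category[1], "ted_embedded")
    }

    # split cohort: one dpam domain vs two ted halves -> each half is fully
    # covered (f_ted = 1) but covers only half the dpam domain (f_dpam =
    # 0.5 < 0.6), i.e. each half reads as embedded in the dpam domain
    one <- list(DomainAnnotation("P", "D01", "1-200", "dpam"))
    halves <- perturbAnnotation(
        list(DomainAnnotation("P", "T01", "1-200", "truth")),
        list(op = "split_at", domain = 1, position = 101))
    pairs <- pairDomains(one, halves)
    expect_equal(nrow(pairs), 2L)
    expect_true(all(pairs$f_ted == 1))
    expect_true(all(pairs$f_dpam == 0.5))
    expect_true(all(pairs$category == "ted_embedded"))
    # a 60/40 split leaves the large half at f_dpam = 0.6: boundary ->
    # intermediate under strict inequalities
    skew <- pairDomains(one, perturbAnnotation(
        list(DomainAnnotation("P", "T01", "1-200", "truth")),
        list(op = "split_at", domain = 1, position = 121)))
    expect_equal(sort(skew$category), c("intermediate", "ted_embedded"))
})
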