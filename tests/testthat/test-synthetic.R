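test_that("generated PAE recovers the configured block means", {
    params <- generatorParams(seed = 7)
    tr <- genProtein(params)
    doms <- truthDomains(tr)
    expect_length(doms, 2L)
    pae <- paeMatrix(truthProtein(tr))
    r1 <- residueSet(domainRanges(doms[[1]]))
    r2 <- residueSet(domainRanges(doms[[2]]))
    intra <- c(pae[r1, r1][upper.tri(pae[r1, r1])],
               pae[r2, r2][upper.tri(pae[r2, r2])])
    inter <- as.vector(pae[r1, r2])
    expect_lt(abs(mean(intra) - params$pae_intra[1]), 0.5)
    expect_lt(abs(mean(inter) - params$pae_inter[1]), 0.5)
    # disordered rows sit near the disorder mean
    dis <- residueSet(disorderedRanges(tr))
    expect_lt(abs(mean(pae[dis, ]) - params$pae_disorder_mean), 1.5)
    # clipping
    expect_gte(min(pae), 0.2)
    expect_lte(max(pae), 31.75)
})

test_that("single-domain, no-tail proteins span the full length", {
    params <- generatorParams(n_domains = 1, tail_disorder = c(0, 0),
                              seed = 3)
    tr <- genProtein(params)
    doms <- truthDomains(tr)
    expect_length(doms, 1L)
    expect_equal(totalLength(domainRanges(doms[[1]])),
                 proteinLength(truthProtein(tr)))
    expect_null(disorderedRanges(tr))
    # one-domain PAE: every ordered off-diagonal entry from the intra block
    pae <- paeMatrix(truthProtein(tr))
    off <- pae[upper.tri(pae)]
    expect_lt(abs(mean(off) - params$pae_intra[1]), 0.5)
})

test_that("identical seeds give bit-identical ground truths", {
    a <- genProtein(generatorParams(seed = 11))
    b <- genProtein(generatorParams(seed = 11))
    expect_identical(caCoords(truthProtein(a)), caCoords(truthProtein(b)))
    expect_identical(paeMatrix(truthProtein(a)), paeMatrix(truthProtein(b)))
    expect_identical(sseLabels(truthProtein(a)), sseLabels(truthProtein(b)))
    c <- genProtein(generatorParams(seed = 12))
    expect_false(identical(caCoords(truthProtein(a)),
                           caCoords(truthProtein(c))))
})

test_that("geometric separability holds at the default spacing", {
    for (s in c(1, 5, 9)) {
        tr <- genProtein(generatorParams(seed = s))
        co <- caCoords(truthProtein(tr))
        doms <- truthDomains(tr)
        r1 <- residueSet(domainRanges(doms[[1]]))
        r2 <- residueSet(domainRanges(doms[[2]]))
        d <- as.matrix(dist(co))
        expect_lt(mean(d[r1, r1]), mean(d[r1, r2]))
        expect_lt(mean(d[r2, r2]), mean(d[r1, r2]))
    }
})

test_that("support matrices have the configured block rates", {
    params <- generatorParams(seed = 21)
    tr <- genProtein(params)
    set.seed(99)
    s <- genSupport(tr, params)
    doms <- truthDomains(tr)
    r1 <- residueSet(domainRanges(doms[[1]]))
    r2 <- residueSet(domainRanges(doms[[2]]))
    expect_lt(abs(mean(s[r1, r1][upper.tri(s[r1, r1])]) -
                  params$support_intra), 0.05)
    expect_lt(abs(mean(s[r1, r2]) - params$support_inter), 0.05)
    dis <- residueSet(disorderedRanges(tr))
    expect_true(all(s[dis, ] == 0) && all(s[, dis] == 0))
    expect_identical(s, t(s))
})

test_that("perturbations follow the stated residue arithmetic", {
    parent <- list(DomainAnnotation("P", "T01", "1-370", "truth"))
    # carving an insert out of a domain leaves insert + remainder
    ted <- perturbAnnotation(parent, list(
        op = "carve_insertion", domain = 1,
        carve = parseRangeString("198-234,282-371")))
    expect_length(ted, 2L)
    expect_equal(formatRangeString(domainRanges(ted[[1]])), "1-197,235-281")
    expect_equal(formatRangeString(domainRanges(ted[[2]])), "198-234,282-370")
    expect_true(all(vapply(ted, domainSource, character(1)) == "ted"))

    two <- list(DomainAnnotation("P", "T01", "1-200", "truth"))
    halves <- perturbAnnotation(two, list(op = "split_at", domain = 1,
                                          position = 101))
    expect_equal(formatRangeString(domainRanges(halves[[1]])), "1-100")
    expect_equal(formatRangeString(domainRanges(halves[[2]])), "101-200")

    pair <- list(DomainAnnotation("P", "T01", "1-100", "truth"),
                 DomainAnnotation("P", "T02", "121-200", "truth"))
    merged <- perturbAnnotation(pair, list(op = "merge", i = 1, j = 2))
    expect_length(merged, 1L)
    expect_equal(formatRangeString(domainRanges(merged[[1]])),
                 "1-100,121-200")

    trimmed <- perturbAnnotation(two, list(op = "trim_termini", domain = 1,
                                           k = 5))
    expect_equal(formatRangeString(domainRanges(trimmed[[1]])), "6-195")

    expect_error(perturbAnnotation(two, list(op = "split_at", domain = 1,
                                             position = 300)), "bisect")
    expect_error(perturbAnnotation(two, list(op = "carve_insertion",
                                             domain = 1,
                                             carve = parseRangeString("500-600"))),
                 "outside")
})

test_that("split, merge and carve conserve the parent residue set", {
    set.seed(17)
    for (i in 1:20) {
        tr <- genProtein(generatorParams(seed = 300 + i))
        doms <- truthDomains(tr)
        parentRes <- sort(unlist(lapply(doms, function(d)
            residueSet(domainRanges(d)))))
        res <- residueSet(domainRanges(doms[[1]]))
        specs <- list(
            list(op = "split_at", domain = 1,
                 position = res[length(res) %/% 2]),
            list(op = "merge", i = 1, j = 2),
            list(op = "carve_insertion", domain = 1,
                 carve = segmentsFromResidues(
                     res[10:(10 + length(res) %/% 3)])))
        for (spec in specs) {
            ted <- perturbAnnotation(doms, spec)
            tedRes <- sort(unlist(lapply(ted, function(d)
                residueSet(domainRanges(d)))))
            expect_identical(tedRes, parentRes)
        }
    }
})

test_that("mock metadata has the configured marginals", {
    annots <- lapply(1:2000, function(i)
        DomainAnnotation(sprintf("P%04d", i), "D01", "1-100", "dpam"))
    meta <- genMetadata(annots, seed = 5, daliMean = 9.18, daliSd = 6.99)
    expect_true(all(meta$best_seq_rel >= 0 & meta$best_seq_rel <= 1))
    expect_true(all(meta$confidence >= 0 & meta$confidence <= 1))
    expect_lt(abs(mean(meta$dali_z) - 9.18) / 9.18, 0.1)
    expect_true(all(meta$architecture %in% ecodArchitectures()))
    expect_identical(meta, genMetadata(annots, seed = 5,
                                       daliMean = 9.18, daliSd = 6.99))
})

test_that("cohort fixtures are complete and byte-identical on regeneration", {
    dir1 <- withr::local_tempdir()
    dir2 <- withr::local_tempdir()
    params <- generatorParams(seed = 31, domain_length = c(40, 60),
                              tail_disorder = c(3, 8))
    co1 <- genCohort(5, params, dir = dir1)
    co2 <- genCohort(5, params, dir = dir2)
    expect_setequal(sort(unique(co1$modes)),
                    c("carve", "split", "merge", "trim"))
    for (f in list.files(dir1)) {
        expect_identical(readLines(file.path(dir1, f)),
                         readLines(file.path(dir2, f)))
    }
    # one PDB + one PAE JSON per protein, chopping rows shared
    expect_length(list.files(dir1, pattern = "\\.pdb$"), 5L)
    expect_length(list.files(dir1, pattern = "_pae\\.json$"), 5L)
    chop <- readChoppingTable(file.path(dir1, "chopping.tsv"))
    src <- vapply(chop, domainSource, character(1))
    expect_true(all(c("truth", "ted") %in% src))
    # fixture files reassemble into valid models matching the truths
    got <- readCaCoordinates(file.path(dir1, "SYN0001.pdb"))
    pae <- readPaeJson(file.path(dir1, "SYN0001_pae.json"))
    model <- assembleModel(got, pae)
    expect_equal(proteinLength(model),
                 proteinLength(truthProtein(co1$truths[[1]])))
    expect_equal(readGeneratorConfig(file.path(dir1, "config.txt"))$seed,
                 params$seed)
})
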