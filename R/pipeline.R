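#' Run the whole analysis on a synthetic cohort
#'
#' Chains every stage with one master seed: simulate a cohort
#' ([genCohort()]), parse each protein from its PAE/coordinates/support
#' ([parseProtein()]), attach mock assignment metadata and SSE counts to
#' the parsed domains, classify them ([classifyRecords()]), compare the
#' parsed chopping against the perturbed alternative chopping
#' ([compareCohort()]), and tabulate everything ([summarizeCohort()]).
#'
#' @param nProteins Number of synthetic proteins.
#' @param params A [generatorParams()]; `params$seed` seeds the run.
#' @param cfg A [parserConfig()].
#' @param th A [defaultThresholds()].
#' @param perturbMix Perturbation-mode weights, see [genCohort()].
#' @param dir Optional directory: fixture files and report tables are
#'   written beneath it.
#' @return A list with `cohort`, `parsed` (per-protein
#'   [ParsedDomain-class] lists), `dpamAnnotations`, `records`
#'   (classified), `pairs`, `summary`.
#' @export
runPipeline <- function(nProteins = 20, params = generatorParams(),
                        cfg = parserConfig(), th = defaultThresholds(),
                        perturbMix = c(carve = 0.25, split = 0.25,
                                       merge = 0.25, trim = 0.25),
                        dir = NULL) {
    cohort <- genCohort(nProteins, params, perturbMix,
                        dir = if (is.null(dir)) NULL
                              else file.path(dir, "fixture"))
    parsed <- vector("list", nProteins)
    dpam <- list()
    for (i in seq_len(nProteins)) {
        prot <- truthProtein(cohort$truths[[i]])
        parsed[[i]] <- parseProtein(prot, cohort$supports[[i]], cfg)
        dpam <- c(dpam, parsedToAnnotations(parsed[[i]], proteinId(prot)))
    }
    records <- choppingFrame(dpam)
    meta <- genMetadata(dpam, seed = .deriveSeed(params$seed, 999983L))
    records <- cbind(records,
                     meta[, setdiff(names(meta),
                                    c("protein_id", "domain_id"))])
    sseCounts <- t(vapply(seq_along(dpam), function(k) {
        prot <- truthProtein(cohort$truths[[
            match(proteinId(dpam[[k]]),
                  vapply(cohort$truths,
                         function(tr) proteinId(truthProtein(tr)),
                         character(1)))]])
        countSse(sseLabels(prot), domainRanges(dpam[[k]]), th)
    }, integer(2)))
    records$n_helix <- sseCounts[, "n_helix"]
    records$n_strand <- sseCounts[, "n_strand"]
    records <- classifyRecords(records, th)
    pairs <- compareCohort(dpam, unlist(cohort$tedAnnotations), th)
    summary <- summarizeCohort(records, pairs, th)
    if (!is.null(dir)) {
        writeChoppingTable(dpam, file.path(dir, "dpam_chopping.tsv"))
        writeReportTsv(records, file.path(dir, "records.tsv"))
        writeReportTsv(pairs, file.path(dir, "overlap_pairs.tsv"))
        renderReport(summary, file.path(dir, "report"))
    }
    list(cohort = cohort, parsed = parsed, dpamAnnotations = dpam,
         records = records, pairs = pairs, summary = summary)
}
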