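#' Rounded percentage on the 0-100 scale
#'
#' `100 * numerator / denominator`, rounded half-away-from-zero to
#' `decimals` places (the convention of printed tables, unlike R's
#' banker's rounding).
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param decimals Decimal places kept.
#' @return Numeric percentage.
#' @examples
#' percentage(2490, 8044)      # 31
#' percentage(528, 2490, 1)    # 21.2
#' @export
percentage <- function(numerator, denominator, decimals = 0) {
    if (any(denominator <= 0))
        stop("denominator must be positive")
    x <- 100 * numerator / denominator
    f <- 10^decimals
    sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Tabulate assignment categories
#'
#' @param records Data frame with a `category` column (see
#'   [classifyRecords()]).
#' @return Data frame with one row per assignment category: `category`,
#'   `count`, `percent` (integer percent of the total).
#' @export
tabulateAssignment <- function(records) {
    if (nrow(records) > 0 && any(is.na(records$category)))
        stop("every record must be categorized first")
    counts <- vapply(.assignmentCategories, function(cat)
        sum(records$category == cat), integer(1))
    if (nrow(records) > 0 && sum(counts) != nrow(records))
        stop("unknown category label(s): ",
             paste(setdiff(unique(records$category), .assignmentCategories),
                   collapse = ", "))
    total <- sum(counts)
    data.frame(category = .assignmentCategories,
               count = unname(counts),
               percent = if (total > 0) percentage(unname(counts), total)
                         else rep(0, length(counts)),
               stringsAsFactors = FALSE)
}

#' Tabulate overlap categories, globally and per architecture
#'
#' @param pairs Overlap-pair data frame from [compareCohort()].
#' @param records Optional record data frame carrying `protein_id`,
#'   `domain_id` and `architecture` for the dpam-side domains; pairs whose
#'   domain lacks a label are counted under `"unlabeled"`.
#' @return A list with `global` (one row per overlap category: `category`,
#'   `count`, `percent`) and `by_architecture` (rows `architecture` x
#'   `category` with counts; `NULL` when `records` is missing).
#' @export
tabulateOverlap <- function(pairs, records = NULL) {
    counts <- vapply(.overlapCategories, function(cat)
        sum(pairs$category == cat), integer(1))
    total <- sum(counts)
    if (nrow(pairs) > 0 && total != nrow(pairs))
        stop("unknown overlap category label(s)")
    global <- data.frame(category = .overlapCategories,
                         count = unname(counts),
                         percent = if (total > 0)
                             percentage(unname(counts), total)
                         else rep(0, length(counts)),
                         stringsAsFactors = FALSE)
    byArch <- NULL
    if (!is.null(records)) {
        key <- paste(records$protein_id, records$domain_id, sep = "\r")
        arch <- records$architecture[match(
            paste(pairs$protein_id, pairs$dpam_id, sep = "\r"), key)]
        arch[is.na(arch) | !nzchar(arch)] <- "unlabeled"
        if (nrow(pairs) > 0) {
            tab <- table(architecture = arch,
                         category = factor(pairs$category,
                                           levels = .overlapCategories))
            byArch <- as.data.frame(tab, stringsAsFactors = FALSE)
            names(byArch)[3L] <- "count"
            byArch <- byArch[order(byArch$architecture, byArch$category), ,
                             drop = FALSE]
            rownames(byArch) <- NULL
        } else {
            byArch <- data.frame(architecture = character(0),
                                 category = character(0),
                                 count = integer(0))
        }
    }
    list(global = global, by_architecture = byArch)
}

#' Summary statistics of the structural Z-score
#'
#' @param dali_z Numeric vector of Z-scores (or a record data frame with a
#'   `dali_z` column).
#' @return Named vector `c(mean, median, sd, min, max)`; the sample
#'   (n - 1) standard deviation is used, reported as 0 with a warning for
#'   a single value.
#' @export
summarizeDali <- function(dali_z) {
    if (is.data.frame(dali_z))
        dali_z <- dali_z$dali_z
    if (length(dali_z) == 0L || any(is.na(dali_z)))
        stop("dali_z must be a non-empty vector without NA")
    s <- if (length(dali_z) == 1L) {
        warning("standard deviation undefined for a single value; ",
                "reporting 0")
        0
    } else {
        stats::sd(dali_z)
    }
    c(mean = mean(dali_z), median = stats::median(dali_z), sd = s,
      min = min(dali_z), max = max(dali_z))
}

#' Distribution of Best_Seq_Rel scores
#'
#' Reports both the four disjoint bins of [binBestSeqRel()] and the
#' cumulative "below" counts that printed summaries mix with them
#' (`below_low` = low + very_low, `below_very_low` = very_low).
#'
#' @param best_seq_rel Numeric vector in \[0, 1\] (or a record data frame
#'   with a `best_seq_rel` column).
#' @param th A [defaultThresholds()].
#' @return A list with `bins` (data frame `bin`, `count`, `percent`) and
#'   `cumulative` (named counts `below_low`, `below_very_low`).
#' @export
seqrelDistribution <- function(best_seq_rel, th = defaultThresholds()) {
    if (is.data.frame(best_seq_rel))
        best_seq_rel <- best_seq_rel$best_seq_rel
    n <- length(best_seq_rel)
    bins <- if (n) binBestSeqRel(best_seq_rel, th) else character(0)
    counts <- vapply(.seqrelBins, function(b) sum(bins == b), integer(1))
    data <- data.frame(bin = .seqrelBins, count = unname(counts),
                       percent = if (n > 0) percentage(unname(counts), n)
                                 else rep(0, length(counts)),
                       stringsAsFactors = FALSE)
    list(bins = data,
         cumulative = c(below_low = unname(counts["low"] +
                                          counts["very_low"]),
                        below_very_low = unname(counts["very_low"])))
}

#' Build the full summary report for a cohort
#'
#' @param records Classified record data frame ([classifyRecords()]) with
#'   metadata columns (`best_seq_rel`, `dali_z`, `architecture`,
#'   `n_helix`, `n_strand`, `n_tm`).
#' @param pairs Overlap-pair data frame ([compareCohort()]).
#' @param th A [defaultThresholds()].
#' @return A `domainSummary` list with components `assignment`, `overlap`,
#'   `seqrel`, `dali`, `sse`, `totals`.
#' @export
summarizeCohort <- function(records, pairs, th = defaultThresholds()) {
    assignment <- tabulateAssignment(records)
    overlap <- tabulateOverlap(pairs, records)
    seqrel <- seqrelDistribution(records, th)
    dali <- if (nrow(records)) summarizeDali(records)
            else c(mean = 0, median = 0, sd = 0, min = 0, max = 0)
    sse <- c(mean_helix = if (nrow(records)) mean(records$n_helix) else 0,
             mean_strand = if (nrow(records)) mean(records$n_strand) else 0,
             mean_tm = if (nrow(records)) mean(records$n_tm) else 0)
    structure(list(assignment = assignment, overlap = overlap,
                   seqrel = seqrel, dali = dali, sse = sse,
                   totals = c(domains = nrow(records),
                              pairs = nrow(pairs))),
              class = "domainSummary")
}

#' @export
print.domainSummary <- function(x, ...) {
    cat("Domain cohort summary\n")
    cat(sprintf("  %d domains, %d significant overlap pairs\n\n",
                x$totals["domains"], x$totals["pairs"]))
    cat("Assignment categories:\n")
    for (i in seq_len(nrow(x$assignment)))
        cat(sprintf("  %-16s %6d (%g%%)\n", x$assignment$category[i],
                    x$assignment$count[i], x$assignment$percent[i]))
    cat("\nOverlap categories:\n")
    for (i in seq_len(nrow(x$overlap$global)))
        cat(sprintf("  %-16s %6d (%g%%)\n", x$overlap$global$category[i],
                    x$overlap$global$count[i], x$overlap$global$percent[i]))
    cat("\nBest_Seq_Rel bins:\n")
    for (i in seq_len(nrow(x$seqrel$bins)))
        cat(sprintf("  %-16s %6d (%g%%)\n", x$seqrel$bins$bin[i],
                    x$seqrel$bins$count[i], x$seqrel$bins$percent[i]))
    cat(sprintf("\nStructural Z-score: mean %.2f, median %.2f, sd %.2f, range %.2f-%.2f\n",
                x$dali["mean"], x$dali["median"], x$dali["sd"],
                x$dali["min"], x$dali["max"]))
    cat(sprintf("SSE per domain: %.2f helices, %.2f strands, %.2f TM segments\n",
                x$sse["mean_helix"], x$sse["mean_strand"], x$sse["mean_tm"]))
    invisible(x)
}

#' Render a summary report to disk
#'
#' Writes `assignment.tsv`, `overlap.tsv`, `overlap_by_architecture.tsv`
#' (when available), `seqrel.tsv`, `dali.tsv` and a human-readable
#' `report.txt` into `dir`, all deterministically ordered.
#'
#' @param summary A `domainSummary` from [summarizeCohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
renderReport <- function(summary, dir) {
    stopifnot(inherits(summary, "domainSummary"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
        writeReportTsv(summary$assignment, file.path(dir, "assignment.tsv")),
        writeReportTsv(summary$overlap$global, file.path(dir, "overlap.tsv")),
        writeReportTsv(summary$seqrel$bins, file.path(dir, "seqrel.tsv")),
        writeReportTsv(data.frame(statistic = names(summary$dali),
                                  value = unname(summary$dali)),
                       file.path(dir, "dali.tsv")))
    if (!is.null(summary$overlap$by_architecture))
        paths <- c(paths, writeReportTsv(
            summary$overlap$by_architecture,
            file.path(dir, "overlap_by_architecture.tsv")))
    txt <- file.path(dir, "report.txt")
    con <- file(txt, open = "wt", encoding = "UTF-8")
    sink(con)
    print(summary)
    sink()
    close(con)
    invisible(c(paths, txt))
}
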