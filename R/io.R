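#' Read a domain chopping table
#'
#' A chopping table is a TSV with one row per domain and columns
#' `protein_id`, `domain_id`, `ranges` (a range string, see
#' [parseRangeString()]) and `source` (`dpam`, `ted` or `truth`).
#'
#' @param path Path to the TSV file.
#' @return A list of [DomainAnnotation-class] objects, in file order.
#' @export
readChoppingTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    required <- c("protein_id", "domain_id", "ranges", "source")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("chopping table lacks column(s): ",
             paste(missing, collapse = ", "))
    bad <- setdiff(unique(df$source), .domainSources)
    if (length(bad))
        stop("unknown source label(s): ", paste(bad, collapse = ", "))
    key <- paste(df$protein_id, df$domain_id, df$source, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate (protein_id, domain_id, source): ",
             gsub("\r", "/", key[duplicated(key)][1L]))
    lapply(seq_len(nrow(df)), function(i)
        DomainAnnotation(df$protein_id[i], df$domain_id[i],
                         parseRangeString(df$ranges[i]), df$source[i]))
}

#' Write a domain chopping table
#'
#' Inverse of [readChoppingTable()]: a write/read round trip preserves
#' every field (ranges are stored normalized).
#'
#' @param annotations A list of [DomainAnnotation-class] objects.
#' @param path Output TSV path.
#' @return Invisibly, the data frame that was written.
#' @export
writeChoppingTable <- function(annotations, path) {
    df <- choppingFrame(annotations)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(df)
}

#' Flatten annotations to a chopping data frame
#'
#' @param annotations A list of [DomainAnnotation-class] objects.
#' @return A data frame with columns `protein_id`, `domain_id`, `ranges`,
#'   `length`, `source`.
#' @export
choppingFrame <- function(annotations) {
    stopifnot(all(vapply(annotations, is, logical(1), "DomainAnnotation")))
    data.frame(
        protein_id = vapply(annotations, proteinId, character(1)),
        domain_id = vapply(annotations, domainId, character(1)),
        ranges = vapply(annotations, function(a)
            formatRangeString(domainRanges(a)), character(1)),
        length = vapply(annotations, function(a)
            totalLength(domainRanges(a)), integer(1)),
        source = vapply(annotations, domainSource, character(1)),
        stringsAsFactors = FALSE)
}

#' Read a PAE matrix from AlphaFold-DB style JSON
#'
#' Accepts both common dialects: a JSON array holding one object with key
#' `"predicted_aligned_error"` (a list of rows), and the flat object with
#' key `"pae"`. Distance-style payloads (`residue1`/`residue2`/`distance`
#' triplets) are rejected. Values outside \[0, 35\] Angstrom are clipped
#' with a warning.
#'
#' @param path Path to the JSON file.
#' @return A square numeric matrix of PAE values in Angstrom.
#' @export
readPaeJson <- function(path) {
    obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                              simplifyVector = FALSE)
    # unwrap the AFDB top-level one-element array
    if (is.list(obj) && length(obj) >= 1L && is.null(names(obj)) &&
        is.list(obj[[1L]]) && !is.null(names(obj[[1L]])))
        obj <- obj[[1L]]
    if (!is.null(obj$residue1) || !is.null(obj$distance))
        stop("distance-style PAE payloads are not supported; ",
             "expected 'predicted_aligned_error' or 'pae'")
    rows <- obj$predicted_aligned_error
    if (is.null(rows))
        rows <- obj$pae
    if (is.null(rows))
        stop("no 'predicted_aligned_error' or 'pae' key in ", path)
    n <- length(rows)
    lens <- lengths(rows)
    if (n == 0L || any(lens != n))
        stop("PAE payload is not square (", n, " rows, row lengths ",
             paste(unique(lens), collapse = "/"), ")")
    m <- matrix(as.numeric(unlist(rows, use.names = FALSE)),
                nrow = n, byrow = TRUE)
    if (any(is.na(m)))
        stop("non-numeric entries in PAE payload")
    if (any(m < 0) || any(m > 35)) {
        warning("PAE values outside [0, 35] clipped")
        m <- pmin(pmax(m, 0), 35)
    }
    m
}

#' Write a PAE matrix as AlphaFold-DB style JSON
#'
#' @param pae Square numeric matrix.
#' @param path Output path.
#' @param digits Decimal places kept in the JSON (AFDB ships 2).
#' @return Invisibly, `path`.
#' @export
writePaeJson <- function(pae, path, digits = 2) {
    stopifnot(is.matrix(pae), nrow(pae) == ncol(pae))
    payload <- list(list(
        predicted_aligned_error = round(unname(pae), digits),
        max_predicted_aligned_error = 31.75))
    writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE),
               path)
    invisible(path)
}

#' Read CA coordinates (and pLDDT) from a PDB file
#'
#' Consumes the CA atoms of a single-chain PDB file, ordered by residue
#' sequence number. The B-factor column is returned as pLDDT, following the
#' AlphaFold convention of storing per-residue confidence there.
#'
#' @param path Path to the PDB file.
#' @param proteinId Identifier for the protein; defaults to the file name
#'   without extension.
#' @return A list with elements `proteinId`, `length`, `caCoords`
#'   (length x 3 matrix) and `plddt`. Assemble a full [ProteinModel-class]
#'   with [assembleModel()] once the PAE matrix is read.
#' @export
readCaCoordinates <- function(path,
                              proteinId = sub("\\.[^.]*$", "", basename(path))) {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
    at <- pdb$atom[sel$atom, , drop = FALSE]
    if (nrow(at) == 0L)
        stop("no CA atoms in ", path)
    if (anyDuplicated(at$resno))
        stop("duplicate residue numbers in ", path)
    at <- at[order(at$resno), , drop = FALSE]
    list(proteinId = proteinId,
         length = nrow(at),
         caCoords = unname(as.matrix(at[, c("x", "y", "z")])),
         plddt = as.numeric(at$b))
}

#' Write CA-only PDB for a set of coordinates
#'
#' @param caCoords length x 3 matrix of CA coordinates (Angstrom).
#' @param path Output path.
#' @param plddt Optional per-residue scores written to the B-factor column.
#' @return Invisibly, `path`.
#' @export
writeCaPdb <- function(caCoords, path, plddt = NULL) {
    caCoords <- as.matrix(caCoords)
    n <- nrow(caCoords)
    b <- if (is.null(plddt)) rep(0, n) else as.numeric(plddt)
    bio3d::write.pdb(file = path, xyz = as.numeric(t(caCoords)),
                     resno = seq_len(n), resid = rep("ALA", n),
                     elety = rep("CA", n), chain = rep("A", n),
                     o = rep(1, n), b = round(b, 2))
    invisible(path)
}

#' Assemble a ProteinModel from parsed coordinate and PAE inputs
#'
#' @param coords The list returned by [readCaCoordinates()].
#' @param pae A square PAE matrix, e.g. from [readPaeJson()].
#' @param sse Optional per-residue secondary-structure labels.
#' @return A [ProteinModel-class].
#' @export
assembleModel <- function(coords, pae, sse = NULL) {
    if (coords$length != nrow(pae))
        stop(sprintf("CA count (%d) does not match PAE dimension (%d) for %s",
                     coords$length, nrow(pae), coords$proteinId))
    ProteinModel(coords$proteinId, coords$caCoords, pae,
                 plddt = coords$plddt, sse = sse)
}

#' Write a report table as TSV
#'
#' @param table A data frame (rows sharing one column schema).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeReportTsv <- function(table, path) {
    if (!is.data.frame(table))
        stop("table must be a data frame")
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a report table written by [writeReportTsv()]
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
readReportTsv <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}
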