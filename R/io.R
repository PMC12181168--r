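#' @importFrom utils read.delim write.table
NULL

# Pinned tabular dialect: tab separator, decimal point, UTF-8, no quoting.
.readTsv <- function(path, ...) {
    read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE, quote = "", comment.char = "", ...)
}

.writeTsv <- function(df, path) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    out <- df
    for (j in which(num)) {
        x <- df[[j]]
        if (is.integer(x)) next
        out[[j]] <- vapply(x, function(v) {
            if (is.na(v)) "NA" else sprintf("%.17g", v)
        }, character(1))
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read and write raw count matrices
#'
#' Counts travel as TSV with a header row of sample identifiers and the
#' gene identifier in the first column. Gene identifiers are opaque,
#' case-sensitive strings; rows and columns keep file order. Cells must be
#' non-negative integers.
#'
#' @param path TSV file path.
#' @return \code{readCounts}: an integer matrix with gene row names and
#'   sample column names.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(0:3, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' writeCounts(m, f)
#' readCounts(f)
#' @export
readCounts <- function(path) {
    df <- .readTsv(path)
    if (ncol(df) < 2L)
        stop("count TSV needs a gene id column plus at least one sample")
    ids <- as.character(df[[1L]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicated gene id(s) in ", path, ": ",
             paste(unique(dup), collapse = ", "))
    m <- as.matrix(df[, -1L, drop = FALSE])
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf(
            "non-integer or negative count at gene '%s', sample '%s'",
            ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    m
}

#' @rdname readCounts
#' @param counts integer matrix with dimnames.
#' @param geneColumn header of the gene identifier column.
#' @export
writeCounts <- function(counts, path, geneColumn = "gene_id") {
    df <- data.frame(rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- geneColumn
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a sample metadata table
#'
#' Expects columns \code{sample_id}, \code{subject_id}, \code{cohort}
#' (\code{young}/\code{old}) and \code{timepoint} (\code{pre}/\code{post}).
#' Pairing invariants (one pre and one post per subject, cohort constant
#' within subject) are enforced when the table is combined with counts in
#' \code{\link{PairedCohortExperiment}}.
#'
#' @param path TSV file path.
#' @return data.frame with the four columns above.
#' @export
readSampleTable <- function(path) {
    df <- .readTsv(path)
    need <- c("sample_id", "subject_id", "cohort", "timepoint")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("sample table lacks columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id in ", path)
    bad <- setdiff(unique(df$cohort), .COHORTS)
    if (length(bad))
        stop("unknown cohort label(s): ", paste(bad, collapse = ", "),
             "; accepted: ", paste(.COHORTS, collapse = ", "))
    bad <- setdiff(unique(df$timepoint), .TIMEPOINTS)
    if (length(bad))
        stop("unknown timepoint label(s): ", paste(bad, collapse = ", "),
             "; accepted: ", paste(.TIMEPOINTS, collapse = ", "))
    df[need]
}

#' @rdname readSampleTable
#' @param samples data.frame as returned by \code{readSampleTable}.
#' @export
writeSampleTable <- function(samples, path) {
    .writeTsv(samples[c("sample_id", "subject_id", "cohort", "timepoint")],
              path)
}

#' Read and write subject phenotype tables
#'
#' One row per (subject, phenotype) with the pre- and post-training value;
#' the change \code{delta} is recomputed as \code{post - pre} at full
#' precision on read. Accepted phenotype labels are \code{lean_mass_kg},
#' \code{leg_extension_Nm}, \code{leg_flexion_Nm} and \code{type2_csa_um2}.
#'
#' @param path TSV file path with columns \code{subject_id},
#'   \code{phenotype}, \code{pre}, \code{post}.
#' @return data.frame with columns \code{subject_id}, \code{phenotype},
#'   \code{pre}, \code{post}, \code{delta}.
#' @export
readPhenotypes <- function(path) {
    df <- .readTsv(path)
    need <- c("subject_id", "phenotype", "pre", "post")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(df$phenotype), .PHENOTYPES)
    if (length(bad))
        stop("unknown phenotype label(s): ", paste(bad, collapse = ", "),
             "; accepted: ", paste(.PHENOTYPES, collapse = ", "))
    if (anyDuplicated(df[c("subject_id", "phenotype")]))
        stop("more than one row per (subject, phenotype) in ", path)
    df <- df[need]
    df$delta <- df$post - df$pre
    df
}

#' @rdname readPhenotypes
#' @param phenotypes data.frame as returned by \code{readPhenotypes}.
#' @export
writePhenotypes <- function(phenotypes, path) {
    .writeTsv(phenotypes[c("subject_id", "phenotype", "pre", "post")], path)
}

#' Read and write GMT gene set collections
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name}, \code{description}, then members. Members are deduplicated;
#' empty member lists are kept but reported via \code{message}.
#'
#' @param path GMT file path.
#' @return \code{readGmt}: a \linkS4class{GeneSetCollection}.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdesc\tA\tB\tA", f)
#' geneSets(readGmt(f))
#' @export
readGmt <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(GeneSetCollection())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 2L)
    if (length(short))
        stop("GMT line ", short[1L], " has fewer than 2 tab-separated fields")
    nm <- vapply(parts, `[[`, character(1), 1L)
    if (anyDuplicated(nm))
        stop("duplicated set name(s) in ", path, ": ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    desc <- vapply(parts, `[[`, character(1), 2L)
    sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
    names(sets) <- nm
    empty <- sum(lengths(sets) == 0L)
    if (empty) message(empty, " gene set(s) with no members in ", path)
    GeneSetCollection(sets, setNames(desc, nm))
}

#' @rdname readGmt
#' @param collection a \linkS4class{GeneSetCollection}; members are written
#'   sorted for a canonical byte representation.
#' @export
writeGmt <- function(collection, path) {
    lines <- vapply(names(collection), function(nm) {
        paste(c(nm, collection@descriptions[[nm]],
                sort(collection@sets[[nm]])), collapse = "\t")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Write a named list of result tables as TSV
#'
#' Each element of \code{tables} is written to \code{<dir>/<name>.tsv} with
#' stable column order and full-precision reals (C17 shortest round-trip
#' format), so identical inputs produce byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of written paths.
#' @export
writeResults <- function(tables, dir) {
    stopifnot(is.list(tables), !is.null(names(tables)))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(names(tables), function(nm) {
        .writeTsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }, character(1))
    invisible(paths)
}

#' Import a differential-expression sheet from a supplementary XLSX
#'
#' Thin adapter that converts one sheet of a supplementary workbook to the
#' package's DE table schema. Workbook layouts vary between journals, so
#' the column mapping is supplied by the caller after inspecting the file,
#' not hard-coded.
#'
#' @param path XLSX file path.
#' @param sheet sheet name or index passed to \code{readxl::read_excel}.
#' @param columnMap named character vector mapping the schema fields
#'   \code{gene}, \code{log2FC}, \code{p} (and optionally \code{q}) to the
#'   sheet's column headers.
#' @return data.frame with columns \code{gene}, \code{log2FC}, \code{p} and,
#'   if mapped, \code{q}.
#' @export
readSupplementaryXlsx <- function(path, sheet, columnMap) {
    if (!requireNamespace("readxl", quietly = TRUE))
        stop("readSupplementaryXlsx requires the 'readxl' package")
    need <- c("gene", "log2FC", "p")
    miss <- setdiff(need, names(columnMap))
    if (length(miss))
        stop("columnMap must name: ", paste(miss, collapse = ", "))
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
    absent <- setdiff(unname(columnMap), colnames(df))
    if (length(absent))
        stop("sheet lacks mapped column(s): ", paste(absent, collapse = ", "))
    out <- data.frame(gene = as.character(df[[columnMap[["gene"]]]]),
                      log2FC = as.numeric(df[[columnMap[["log2FC"]]]]),
                      p = as.numeric(df[[columnMap[["p"]]]]),
                      stringsAsFactors = FALSE)
    if ("q" %in% names(columnMap))
        out$q <- as.numeric(df[[columnMap[["q"]]]])
    out
}
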