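#' Subject-specific log2 fold-changes
#'
#' For each subject in scope, the per-gene log2 ratio of post- to
#' pre-training normalized counts with a pseudo-count:
#' \eqn{\log_2((norm_{post}+c)/(norm_{pre}+c))}. This genes-by-subjects
#' matrix is the substrate of the phenotype correlation stage.
#'
#' @param x a \linkS4class{PairedCohortExperiment}; a \code{normalized}
#'   assay is computed if absent.
#' @param prior pseudo-count \eqn{c > 0}; keeps every entry finite.
#' @param scope \code{"combined"} (both cohorts pooled, default),
#'   \code{"young"} or \code{"old"}.
#' @return numeric matrix genes x subjects with attributes \code{prior}
#'   and \code{scope}.
#' @export
subjectLog2FC <- function(x, prior = 0.5,
                          scope = c("combined", "young", "old")) {
    scope <- match.arg(scope)
    stopifnot(is(x, "PairedCohortExperiment"), prior > 0)
    x <- .normalizedAssay(x)
    cd <- colData(x)
    subj <- unique(cd$subject_id[scope == "combined" | cd$cohort == scope])
    key <- paste(cd$subject_id, cd$timepoint)
    pre <- match(paste(subj, "pre"), key)
    post <- match(paste(subj, "post"), key)
    if (anyNA(pre) || anyNA(post))
        stop("subject(s) without a pre/post pair in scope: ",
             paste(subj[is.na(pre) | is.na(post)], collapse = ", "))
    norm <- assay(x, "normalized")
    lfc <- log2(norm[, post, drop = FALSE] + prior) -
        log2(norm[, pre, drop = FALSE] + prior)
    colnames(lfc) <- subj
    attr(lfc, "prior") <- prior
    attr(lfc, "scope") <- scope
    lfc
}

#' Pearson correlation coefficient
#'
#' The moment formula
#' \eqn{r = \sum(x-\bar x)(y-\bar y) / \sqrt{\sum(x-\bar x)^2 \sum(y-\bar y)^2}},
#' returning \code{NA} (an explicit undefined marker) when either vector
#' has zero variance.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return numeric scalar in [-1, 1], or NA when undefined.
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length (", length(x), " vs ",
             length(y), ")")
    if (length(x) < 3) stop("at least 3 observations are required")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("x and y must be finite")
    xc <- x - mean(x); yc <- y - mean(y)
    den <- sqrt(sum(xc^2) * sum(yc^2))
    if (den == 0) return(NA_real_)
    # clamp rounding spill so |r| <= 1 holds exactly
    max(-1, min(1, sum(xc * yc) / den))
}

#' Correlate per-gene fold-changes with a phenotype change
#'
#' For every gene, the Pearson correlation between its subject-specific
#' log2 fold-changes and the subjects' post-minus-pre change in the chosen
#' phenotype. Subjects lacking a delta for that phenotype are dropped
#' pairwise (reported via \code{message}). Positive r means the gene's
#' induction tracks phenotype gain. A two-sided p from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} is reported for reference only; ranking
#' downstream uses r itself.
#'
#' @param lfc matrix from \code{\link{subjectLog2FC}}.
#' @param phenotypes data.frame as from \code{\link{readPhenotypes}}.
#' @param phenotype one of the accepted phenotype labels.
#' @return data.frame (gene, r, n, p); genes with zero fold-change
#'   variance carry NA r and are excluded by \code{\link{rankBy}}.
#' @export
correlateGenes <- function(lfc, phenotypes,
                           phenotype = c("lean_mass_kg", "leg_extension_Nm",
                                         "leg_flexion_Nm", "type2_csa_um2")) {
    phenotype <- match.arg(phenotype)
    ph <- phenotypes[phenotypes$phenotype == phenotype, , drop = FALSE]
    d <- setNames(ph$delta, ph$subject_id)
    common <- intersect(colnames(lfc), names(d[!is.na(d)]))
    dropped <- setdiff(colnames(lfc), common)
    if (length(dropped))
        message(length(dropped), " subject(s) without a ", phenotype,
                " delta dropped: ", paste(dropped, collapse = ", "))
    n <- length(common)
    if (n < 3)
        stop("fewer than 3 subjects with both fold-changes and a ",
             phenotype, " delta")
    m <- lfc[, common, drop = FALSE]
    y <- d[common]
    xc <- m - rowMeans(m)
    yc <- y - mean(y)
    num <- as.numeric(xc %*% yc)
    den <- sqrt(rowSums(xc^2) * sum(yc^2))
    r <- ifelse(den > 0, pmax(-1, pmin(1, num / den)), NA_real_)
    t <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    p <- ifelse(is.na(r), NA_real_,
                ifelse(is.finite(t), 2 * stats::pt(-abs(t), df = n - 2), 0))
    data.frame(gene = rownames(lfc), r = r, n = n, p = p,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Deterministic ranking of a score table
#'
#' Orders genes by score, descending, with exact ties broken by ascending
#' gene identifier; genes with undefined scores are dropped (count
#' reported via \code{message}). The result is the pre-ranked input to
#' \code{\link{gseaPreranked}}.
#'
#' @param scoreTable data.frame with a \code{gene} column and the score
#'   column named by \code{key}.
#' @param key \code{"r"} (phenotype correlation) or \code{"log2FC"}
#'   (training response).
#' @return named numeric vector, scores named by gene, in rank order.
#' @examples
#' rankBy(data.frame(gene = c("A", "B"), r = c(0.5, 0.9)), "r")
#' @export
rankBy <- function(scoreTable, key = c("r", "log2FC")) {
    key <- match.arg(key)
    if (!all(c("gene", key) %in% colnames(scoreTable)))
        stop("scoreTable must have columns 'gene' and '", key, "'")
    s <- scoreTable[[key]]
    bad <- is.na(s) | !is.finite(s)
    if (any(bad))
        message(sum(bad), " gene(s) with undefined ", key, " dropped")
    g <- as.character(scoreTable$gene)[!bad]
    s <- s[!bad]
    if (!length(s)) stop("no genes with a defined ", key, " score to rank")
    if (anyDuplicated(g)) stop("duplicate gene identifiers in scoreTable")
    ord <- order(-s, g)
    setNames(s[ord], g[ord])
}

#' Write a ranked list as a two-column RNK-style TSV
#'
#' @param ranked named numeric vector from \code{\link{rankBy}}.
#' @param path output path.
#' @export
writeRnk <- function(ranked, path) {
    .writeTsv(data.frame(gene = names(ranked), score = unname(ranked),
                         stringsAsFactors = FALSE), path)
}

#' @rdname writeRnk
#' @return \code{readRnk}: the named numeric vector, in file order.
#' @export
readRnk <- function(path) {
    df <- .readTsv(path)
    setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}
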