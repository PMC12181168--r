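#' Median-of-ratios size factors
#'
#' The library-size estimator used throughout the pipeline: for sample
#' \eqn{j}, \eqn{s_j} is the median over reference genes \eqn{g} of
#' \eqn{K_{gj} / GM_g}, where \eqn{GM_g} is the geometric mean of gene
#' \eqn{g} across samples and the median runs over genes whose geometric
#' mean is positive (i.e. genes observed in every sample).
#'
#' @param counts non-negative count matrix (genes x samples), or a
#'   \linkS4class{PairedCohortExperiment}.
#' @return named numeric vector of positive per-sample size factors.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2,
#'             dimnames = list(c("g1", "g2"), c("A", "B")))
#' medianOfRatios(m)  # B has twice A's depth: sqrt(2) vs 1/sqrt(2)
#' @export
setGeneric("medianOfRatios", function(counts) standardGeneric("medianOfRatios"))

#' @rdname medianOfRatios
#' @export
setMethod("medianOfRatios", "matrix", function(counts) {
    if (any(counts < 0)) stop("counts must be non-negative")
    ref <- rowSums(counts > 0) == ncol(counts)
    if (!any(ref))
        stop("no gene has positive counts in every sample; ",
             "filter the matrix to genes detected in all libraries first")
    gm <- exp(rowMeans(log(counts[ref, , drop = FALSE])))
    sf <- apply(counts[ref, , drop = FALSE], 2L,
                function(k) stats::median(k / gm))
    setNames(sf, colnames(counts))
})

#' @rdname medianOfRatios
#' @export
setMethod("medianOfRatios", "PairedCohortExperiment", function(counts) {
    medianOfRatios(assay(counts, "counts"))
})

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its size factor,
#' \eqn{K_{gj}/s_j}. For a \linkS4class{PairedCohortExperiment} the
#' result is returned as a new \code{normalized} assay with the size
#' factors stored in \code{colData(x)$sizeFactor}.
#'
#' @param x count matrix or \linkS4class{PairedCohortExperiment}.
#' @param sizeFactors named positive numeric vector; computed with
#'   \code{\link{medianOfRatios}} when omitted.
#' @return matrix of normalized counts, or the experiment with a
#'   \code{normalized} assay added.
#' @export
setGeneric("normalizeCounts",
           function(x, sizeFactors = NULL) standardGeneric("normalizeCounts"))

#' @rdname normalizeCounts
#' @export
setMethod("normalizeCounts", "matrix", function(x, sizeFactors = NULL) {
    if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(x)
    if (!setequal(names(sizeFactors), colnames(x)))
        stop("size factor names do not match the count matrix samples")
    if (any(sizeFactors <= 0)) stop("size factors must be positive")
    sweep(x, 2L, sizeFactors[colnames(x)], `/`)
})

#' @rdname normalizeCounts
#' @export
setMethod("normalizeCounts", "PairedCohortExperiment",
          function(x, sizeFactors = NULL) {
    k <- assay(x, "counts")
    if (is.null(sizeFactors)) sizeFactors <- medianOfRatios(k)
    SummarizedExperiment::assay(x, "normalized") <-
        normalizeCounts(k, sizeFactors)
    x@colData$sizeFactor <- unname(sizeFactors[colnames(x)])
    x
})

.normalizedAssay <- function(x) {
    if (!"normalized" %in% names(assays(x))) x <- normalizeCounts(x)
    x
}
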