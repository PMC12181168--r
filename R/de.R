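#' @importFrom stats pt phyper p.adjust median
#' @importFrom matrixStats rowSds rowMeans2
NULL

#' Benjamini-Hochberg adjustment with input validation
#'
#' Standard step-up FDR adjustment, returned in input order. A thin,
#' validated front for \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1] (no NA).
#' @return adjusted q-values in [0, 1], same order as \code{p}.
#' @export
bhAdjust <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] with no missing values")
    p.adjust(p, method = "BH")
}

#' Paired differential expression on log2 normalized counts
#'
#' For each gene, the per-subject paired difference
#' \eqn{\delta_s = \log_2(norm_{post}+c) - \log_2(norm_{pre}+c)} is formed
#' within one cohort; the reported log2 fold-change is the mean of
#' \eqn{\delta_s}, the statistic a two-sided paired t with
#' \eqn{n_{subjects}-1} degrees of freedom, and q the Benjamini-Hochberg
#' adjustment across all tested genes. Genes with cohort mean raw count
#' below \code{minMeanCount} are excluded before testing (flagged, with
#' NA statistics) so that near-zero genes do not enter the FDR step.
#'
#' Degenerate genes follow the t-test's continuity limits: zero-variance
#' differences give p = 1 when the mean difference is 0 and p = 0
#' (infinite statistic) otherwise.
#'
#' @param x a \linkS4class{PairedCohortExperiment}; the \code{normalized}
#'   assay is computed via \code{\link{normalizeCounts}} if absent.
#' @param cohort \code{"young"} or \code{"old"}.
#' @param prior pseudo-count \eqn{c} added before taking logs.
#' @param minMeanCount expression filter on the cohort mean raw count.
#' @return data.frame with columns \code{gene}, \code{baseMean},
#'   \code{log2FC}, \code{statistic}, \code{p}, \code{q}, \code{filtered};
#'   filtered genes carry NA in \code{log2FC}, \code{statistic}, \code{p},
#'   \code{q}.
#' @export
pairedDETest <- function(x, cohort = c("young", "old"), prior = 0.5,
                         minMeanCount = 5) {
    cohort <- match.arg(cohort)
    stopifnot(is(x, "PairedCohortExperiment"), prior > 0)
    x <- .normalizedAssay(x)
    cd <- colData(x)
    keep <- cd$cohort == cohort
    subj <- unique(cd$subject_id[keep])
    n <- length(subj)
    if (n < 3)
        stop("cohort '", cohort, "' has ", n,
             " subjects; at least 3 are required for a paired t-test")
    norm <- assay(x, "normalized")
    raw <- assay(x, "counts")
    preCols <- colnames(x)[match(paste(subj, "pre"),
                                 paste(cd$subject_id, cd$timepoint))]
    postCols <- colnames(x)[match(paste(subj, "post"),
                                  paste(cd$subject_id, cd$timepoint))]
    delta <- log2(norm[, postCols, drop = FALSE] + prior) -
        log2(norm[, preCols, drop = FALSE] + prior)
    baseMean <- rowMeans2(raw[, c(preCols, postCols), drop = FALSE])
    tested <- baseMean >= minMeanCount

    lfc <- rowMeans2(delta)
    sd <- rowSds(delta)
    stat <- ifelse(sd > 0, lfc / (sd / sqrt(n)),
                   ifelse(lfc == 0, 0, Inf * sign(lfc)))
    p <- ifelse(is.finite(stat), 2 * pt(-abs(stat), df = n - 1),
                0)
    p[sd == 0 & lfc == 0] <- 1

    out <- data.frame(gene = rownames(x), baseMean = baseMean,
                      log2FC = lfc, statistic = stat, p = p,
                      q = NA_real_, filtered = !tested,
                      stringsAsFactors = FALSE, row.names = NULL)
    out$q[tested] <- bhAdjust(p[tested])
    out$log2FC[!tested] <- NA_real_
    out$statistic[!tested] <- NA_real_
    out$p[!tested] <- NA_real_
    out
}

.sigUp <- function(de, alpha, lfc) {
    de$gene[!de$filtered & de$p < alpha & de$log2FC > lfc]
}
.sigDown <- function(de, alpha, lfc) {
    de$gene[!de$filtered & de$p < alpha & de$log2FC < -lfc]
}

#' Two-cohort overlap classification of DE results
#'
#' Thresholds each cohort's DE table at unadjusted \code{p < alpha} with
#' \code{|log2FC| > lfcThreshold}, then partitions significant genes into
#' six sets: commonly increased/decreased in both cohorts, and uniquely
#' increased/decreased per cohort. A gene absent from one table counts as
#' non-significant there (outer-join semantics). The summary reports the
#' shared sets as a percentage of the union of all increased (resp.
#' decreased) genes, the convention used when quoting the overlap between
#' young and older training responses.
#'
#' @param deYoung,deOld DE tables with columns \code{gene}, \code{log2FC},
#'   \code{p} (a \code{filtered} column is honored when present).
#' @param alpha unadjusted p-value threshold (default 0.05).
#' @param lfcThreshold absolute log2 fold-change threshold (default 0.4).
#' @return object of class \code{DEClassification}: a list with the six
#'   gene sets, the thresholds, and a one-row \code{summary} data.frame of
#'   counts and percentages.
#' @examples
#' tabs <- makeOverlapDETables(nCommonUp = 1, nYoungOnlyUp = 1,
#'                             nOldOnlyUp = 1, nCommonDown = 0,
#'                             nYoungOnlyDown = 0, nOldOnlyDown = 0)
#' classifyDE(tabs$young, tabs$old)
#' @export
classifyDE <- function(deYoung, deOld, alpha = 0.05, lfcThreshold = 0.4) {
    if (alpha <= 0 || lfcThreshold <= 0)
        stop("alpha and lfcThreshold must be positive")
    fix <- function(de) {
        de <- as.data.frame(de)
        if (!"filtered" %in% colnames(de)) de$filtered <- FALSE
        de
    }
    deYoung <- fix(deYoung); deOld <- fix(deOld)
    yUp <- .sigUp(deYoung, alpha, lfcThreshold)
    yDn <- .sigDown(deYoung, alpha, lfcThreshold)
    oUp <- .sigUp(deOld, alpha, lfcThreshold)
    oDn <- .sigDown(deOld, alpha, lfcThreshold)
    sets <- list(common_up = intersect(yUp, oUp),
                 common_down = intersect(yDn, oDn),
                 young_only_up = setdiff(yUp, oUp),
                 young_only_down = setdiff(yDn, oDn),
                 old_only_up = setdiff(oUp, yUp),
                 old_only_down = setdiff(oDn, yDn))
    allUp <- union(yUp, oUp)
    allDn <- union(yDn, oDn)
    summary <- data.frame(
        n_young_up = length(yUp), n_young_down = length(yDn),
        n_old_up = length(oUp), n_old_down = length(oDn),
        n_young_total = length(yUp) + length(yDn),
        n_old_total = length(oUp) + length(oDn),
        n_common_up = length(sets$common_up),
        n_common_down = length(sets$common_down),
        n_young_only_up = length(sets$young_only_up),
        n_young_only_down = length(sets$young_only_down),
        n_old_only_up = length(sets$old_only_up),
        n_old_only_down = length(sets$old_only_down),
        pct_common_up = if (length(allUp))
            100 * length(sets$common_up) / length(allUp) else NA_real_,
        pct_common_down = if (length(allDn))
            100 * length(sets$common_down) / length(allDn) else NA_real_)
    structure(list(sets = sets, alpha = alpha, lfcThreshold = lfcThreshold,
                   summary = summary),
              class = "DEClassification")
}

#' @export
print.DEClassification <- function(x, ...) {
    s <- x$summary
    cat(sprintf("DEClassification (p < %g, |log2FC| > %g)\n", x$alpha,
                x$lfcThreshold))
    cat(sprintf("  young: %d up / %d down; old: %d up / %d down\n",
                s$n_young_up, s$n_young_down, s$n_old_up, s$n_old_down))
    cat(sprintf("  common: %d up (%.1f%%), %d down (%.1f%%)\n",
                s$n_common_up, s$pct_common_up, s$n_common_down,
                s$pct_common_down))
    invisible(x)
}

#' Count significant genes in a DE table
#'
#' Convenience threshold counter exposing both threshold modes: p-value
#' only, or p-value combined with an absolute log2FC cut.
#'
#' @param de DE table (\code{gene}, \code{log2FC}, \code{p}).
#' @param alpha unadjusted p threshold.
#' @param lfcThreshold absolute log2FC threshold, or NULL for p-only mode.
#' @param direction \code{"both"}, \code{"up"} or \code{"down"}.
#' @return integer count.
#' @export
countSignificant <- function(de, alpha = 0.05, lfcThreshold = NULL,
                             direction = c("both", "up", "down")) {
    direction <- match.arg(direction)
    de <- as.data.frame(de)
    if (!"filtered" %in% colnames(de)) de$filtered <- FALSE
    ok <- !de$filtered & !is.na(de$p) & de$p < alpha
    if (!is.null(lfcThreshold)) {
        ok <- ok & switch(direction,
                          both = abs(de$log2FC) > lfcThreshold,
                          up = de$log2FC > lfcThreshold,
                          down = de$log2FC < -lfcThreshold)
    } else {
        ok <- ok & switch(direction, both = TRUE, up = de$log2FC > 0,
                          down = de$log2FC < 0)
    }
    sum(ok)
}

#' Synthetic DE tables with a prescribed overlap structure
#'
#' Fixture builder: constructs a pair of per-cohort DE tables whose
#' thresholded gene sets realise exactly the requested overlap counts
#' (shared and cohort-unique, increased and decreased), plus optional
#' non-significant filler genes shared by both tables. Gene identifiers
#' are synthetic. Used to test and demonstrate
#' \code{\link{classifyDE}}'s set algebra at a known answer, including
#' reconstructing published overlap summaries from their printed counts.
#'
#' @param nCommonUp,nYoungOnlyUp,nOldOnlyUp counts of increased genes
#'   shared / unique to each cohort.
#' @param nCommonDown,nYoungOnlyDown,nOldOnlyDown same for decreased.
#' @param nNull shared non-significant filler genes.
#' @param alpha,lfcThreshold thresholds the tables are built to satisfy.
#' @return list with data.frames \code{young} and \code{old}.
#' @export
makeOverlapDETables <- function(nCommonUp, nYoungOnlyUp, nOldOnlyUp,
                                nCommonDown, nYoungOnlyDown, nOldOnlyDown,
                                nNull = 100, alpha = 0.05,
                                lfcThreshold = 0.4) {
    blocks <- list(
        cu = nCommonUp, yu = nYoungOnlyUp, ou = nOldOnlyUp,
        cd = nCommonDown, yd = nYoungOnlyDown, od = nOldOnlyDown,
        nn = nNull)
    genes <- unlist(lapply(names(blocks), function(b)
        if (blocks[[b]] > 0) sprintf("%s_%04d", b, seq_len(blocks[[b]]))
        else character()))
    lab <- sub("_.*", "", genes)
    sigP <- alpha / 2
    nsP <- min(1, alpha * 10)
    upFC <- lfcThreshold + 0.6
    dnFC <- -(lfcThreshold + 0.6)
    nsFC <- 0
    mk <- function(upLab, dnLab) {
        data.frame(
            gene = genes,
            log2FC = ifelse(lab %in% upLab, upFC,
                            ifelse(lab %in% dnLab, dnFC, nsFC)),
            p = ifelse(lab %in% c(upLab, dnLab), sigP, nsP),
            stringsAsFactors = FALSE)
    }
    list(young = mk(c("cu", "yu"), c("cd", "yd")),
         old = mk(c("cu", "ou"), c("cd", "od")))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a DE gene list relative
#' to a stated universe: with \eqn{k} the overlap between the list and the
#' set (restricted to the universe), the p-value is the upper-tail
#' hypergeometric probability of at least \eqn{k} marked genes when
#' drawing \eqn{|list|} genes from the universe. BH adjustment across
#' tested sets.
#'
#' @param deSet character vector of significant genes (must be contained
#'   in \code{universe}).
#' @param universe character vector of all tested genes.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param minSize,maxSize set-size filter applied after restriction to the
#'   universe.
#' @return data.frame (set, size_universe, overlap, expected, p, q) sorted
#'   by p.
#' @export
oraHypergeometric <- function(deSet, universe, collection, minSize = 2,
                              maxSize = Inf) {
    deSet <- unique(deSet); universe <- unique(universe)
    if (!all(deSet %in% universe))
        stop("deSet must be a subset of the universe (",
             sum(!deSet %in% universe), " gene(s) outside)")
    N <- length(universe); n <- length(deSet)
    rows <- lapply(names(collection), function(nm) {
        S <- intersect(collection@sets[[nm]], universe)
        K <- length(S)
        if (K < minSize || K > maxSize) return(NULL)
        k <- length(intersect(deSet, S))
        data.frame(set = nm, size_universe = K, overlap = k,
                   expected = n * K / N,
                   p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows))
        return(data.frame(set = character(), size_universe = integer(),
                          overlap = integer(), expected = numeric(),
                          p = numeric(), q = numeric()))
    rows$q <- bhAdjust(rows$p)
    rows[order(rows$p, rows$set), , drop = FALSE]
}

#' Exact intersection of two gene lists
#'
#' Case-sensitive set intersection, the primitive behind panel-overlap
#' questions (e.g. how many training-responsive mRNAs fall in an
#' externally supplied stress-response or senescence panel).
#'
#' @param a,b character vectors of gene identifiers.
#' @return character vector of shared identifiers (order of \code{a}),
#'   with the count in attribute \code{n}.
#' @export
intersectGeneLists <- function(a, b) {
    out <- intersect(as.character(a), as.character(b))
    attr(out, "n") <- length(out)
    out
}
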