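#' @importFrom utils combn
NULL

# Running-sum extremes evaluated only at hit positions: between hits the
# sum decays linearly, so the maximum sits immediately after a hit and the
# minimum immediately before one (or at the zero endpoint). O(k) per set.
# pos: sorted hit positions; absw: |score|^w for the whole list.
.esAtPositions <- function(pos, absw, N) {
    k <- length(pos)
    wv <- absw[pos]
    NR <- sum(wv)
    H <- if (NR > 0) cumsum(wv) / NR else seq_len(k) / k
    miss <- (pos - seq_len(k)) / (N - k)
    top <- H - miss
    bottom <- c(0, H[-k]) - miss
    A <- max(top, 0)
    B <- min(bottom, 0)
    # exact-magnitude ties between the extremes occur (e.g. both equal a
    # multiple of the miss step); resolve them to the positive extreme,
    # with a tolerance because A and B come from different expressions
    if (A >= -B - 1e-12) A else B
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list in order; at a member gene the sum rises by
#' \eqn{|score_i|^w / N_R} (with \eqn{N_R} the total weighted hit mass)
#' and at a non-member it falls by \eqn{1/(N - N_h)}. The enrichment score
#' is the running sum's maximal signed deviation from zero; when the
#' positive and negative extremes tie in magnitude, the positive one is
#' reported.
#'
#' @param ranked named numeric vector from \code{\link{rankBy}} (scores
#'   named by gene, descending).
#' @param members character vector of gene-set members.
#' @param weight exponent \eqn{w \ge 0}; 1 is the standard weighted
#'   statistic, 0 the classic unweighted form.
#' @return list with \code{es}, \code{runningSum} (length-N numeric) and
#'   \code{peakIndex} (position of the reported extreme).
#' @examples
#' ranked <- setNames(5:1, paste0("g", 1:5))
#' enrichmentScore(ranked, "g1")$es  # top-ranked singleton: ES = 1
#' @export
enrichmentScore <- function(ranked, members, weight = 1) {
    N <- length(ranked)
    hits <- names(ranked) %in% members
    Nh <- sum(hits)
    if (Nh == 0L) stop("no gene-set member present in the ranked list")
    if (Nh == N) stop("gene set covers the entire ranked list")
    absw <- abs(ranked)^weight
    NR <- sum(absw[hits])
    if (NR == 0)
        stop("all member scores are zero at weight > 0; N_R = 0 leaves ",
             "the hit increment undefined")
    inc <- rep(-1 / (N - Nh), N)
    inc[hits] <- absw[hits] / NR
    running <- cumsum(inc)
    # extremes evaluated analytically at the hit boundaries, so that
    # exact positive/negative ties resolve deterministically (positive
    # wins) instead of on the cumsum's accumulated rounding noise
    pos <- which(hits)
    wv <- absw[pos]
    H <- if (NR > 0) cumsum(wv) / NR else seq_len(Nh) / Nh
    miss <- (pos - seq_len(Nh)) / (N - Nh)
    top <- H - miss
    bottom <- c(0, H[-Nh]) - miss
    A <- max(top, 0)
    B <- min(bottom, 0)
    if (A >= -B - 1e-12) {
        es <- A; peak <- pos[which.max(top)]
    } else {
        es <- B; peak <- pos[which.min(bottom)] - 1L
    }
    list(es = es, runningSum = running, peakIndex = peak)
}

.permNull <- function(ranked, hitIdx, config, seed) {
    N <- length(ranked)
    k <- length(hitIdx)
    absw <- abs(ranked)^config@weight
    es <- .esAtPositions(sort(hitIdx), absw, N)
    nPerm <- as.integer(config@nPerm)
    nSubsets <- choose(N, k)
    if (is.finite(nSubsets) && nSubsets <= nPerm) {
        subsets <- combn(N, k)
        nullES <- apply(subsets, 2L, .esAtPositions, absw = absw, N = N)
        sameSign <- if (es >= 0) nullES >= 0 else nullES < 0
        # exact: the observed subset is among the enumerated ones
        p <- sum(sameSign & abs(nullES) >= abs(es)) / max(1L, sum(sameSign))
        exact <- TRUE
    } else {
        set.seed(as.integer(seed))
        nullES <- vapply(seq_len(nPerm), function(i)
            .esAtPositions(sort(sample.int(N, k)), absw, N), numeric(1))
        sameSign <- if (es >= 0) nullES >= 0 else nullES < 0
        # conditioning on the ES sign keeps the one-sided p uniform under
        # the null; +1 smoothing avoids zero p at finite permutation count
        p <- (1 + sum(sameSign & abs(nullES) >= abs(es))) /
            (1 + sum(sameSign))
        exact <- FALSE
    }
    denom <- mean(abs(nullES[sameSign]))
    nes <- if (any(sameSign) && denom > 0) es / denom else NA_real_
    list(es = es, p = p, nes = nes, nullES = nullES, exact = exact)
}

#' Gene-permutation null for one gene set
#'
#' Holds the ranked scores fixed and redraws the member labels: each
#' permutation samples a random same-size gene subset and recomputes the
#' enrichment score. The one-sided p-value conditions on the sign of the
#' observed score, as in standard pre-ranked GSEA: among null scores of
#' the same sign, it is the smoothed fraction at least as extreme,
#' \eqn{p = (1 + \#extreme)/(1 + \#samesign)}, which is uniform under the
#' null. Whenever the number of
#' distinct subsets \eqn{C(N, k)} does not exceed \code{nPerm}, sampling
#' is replaced by exhaustive enumeration and the p-value is exact.
#'
#' @param ranked named numeric vector (descending scores).
#' @param members gene-set member identifiers.
#' @param config a \linkS4class{GseaConfig}; supplies weight, permutation
#'   count and seed.
#' @return list with \code{es}, \code{p}, \code{nes} (ES over the mean
#'   same-sign null magnitude; NA when no same-sign null exists),
#'   \code{nullES} and \code{exact}.
#' @export
permutationNull <- function(ranked, members, config = gseaConfig()) {
    hitIdx <- which(names(ranked) %in% members)
    if (!length(hitIdx)) stop("no gene-set member present in the ranked list")
    .permNull(ranked, hitIdx, config, config@seed)
}

#' Pre-ranked gene set enrichment analysis
#'
#' For every gene set surviving the size filter: the weighted running-sum
#' enrichment score, a gene-permutation (or exhaustive) null with its
#' one-sided p-value, the normalized enrichment score, the leading edge
#' (members at or before the running-sum peak for positive scores, at or
#' after it for negative), and an FDR across sets. Per-set permutation
#' streams are derived deterministically from the config seed, so results
#' are fully reproducible.
#'
#' @param ranked named numeric vector from \code{\link{rankBy}}.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param config a \linkS4class{GseaConfig}. \code{fdrMethod
#'   "bh_on_perm_p"} (default) applies Benjamini-Hochberg to the
#'   permutation p-values; \code{"gsea_style"} compares each NES against
#'   the sign-matched pooled null NES distribution.
#' @return data.frame (set, size_used, es, nes, p_perm, fdr,
#'   leading_edge) sorted by NES descending; skipped sets and reasons are
#'   attached as attribute \code{skipped}.
#' @export
gseaPreranked <- function(ranked, collection, config = gseaConfig()) {
    if (!length(ranked) || !length(collection))
        stop("ranked list and collection must be non-empty")
    skipped <- list()
    rows <- list()
    nulls <- list()
    for (i in seq_along(names(collection))) {
        nm <- names(collection)[i]
        hitIdx <- which(names(ranked) %in% collection@sets[[nm]])
        k <- length(hitIdx)
        if (k == 0L) {
            skipped[[nm]] <- "no member in ranked list"; next
        }
        if (k < config@minSize || k > config@maxSize) {
            skipped[[nm]] <- sprintf("size %d outside [%g, %g]", k,
                                     config@minSize, config@maxSize)
            next
        }
        if (k == length(ranked)) {
            skipped[[nm]] <- "set covers the entire ranked list"; next
        }
        pn <- .permNull(ranked, hitIdx, config,
                        seed = as.integer(config@seed) + i)
        esFull <- enrichmentScore(ranked, collection@sets[[nm]],
                                  config@weight)
        le <- if (esFull$es >= 0)
            names(ranked)[intersect(seq_len(esFull$peakIndex), hitIdx)]
        else
            names(ranked)[intersect(seq(esFull$peakIndex, length(ranked)),
                                    hitIdx)]
        rows[[nm]] <- data.frame(
            set = nm, size_used = k, es = pn$es, nes = pn$nes,
            p_perm = pn$p,
            leading_edge = paste(le, collapse = ";"),
            stringsAsFactors = FALSE)
        nulls[[nm]] <- pn
    }
    if (length(skipped))
        message(length(skipped), " gene set(s) skipped (",
                paste(sprintf("%s: %s", names(skipped), unlist(skipped)),
                      collapse = "; "), ")")
    if (!length(rows))
        stop("all ", length(collection), " gene sets were filtered out (",
             length(skipped), " skipped)")
    res <- do.call(rbind, rows)
    res$fdr <- if (config@fdrMethod == "bh_on_perm_p") {
        bhAdjust(res$p_perm)
    } else {
        .gseaStyleFdr(res, nulls)
    }
    res <- res[order(-res$nes, res$set),
               c("set", "size_used", "es", "nes", "p_perm", "fdr",
                 "leading_edge")]
    rownames(res) <- NULL
    attr(res, "skipped") <- skipped
    res
}

# Sign-matched pooled-null NES FDR, the native GSEA variant: each null ES
# is normalized by its own set's mean same-sign null magnitude, pooled
# across sets; q(S) is the ratio of the null and observed tail fractions
# beyond |NES(S)|, capped at 1.
.gseaStyleFdr <- function(res, nulls) {
    pooled <- unlist(lapply(nulls, function(pn) {
        pos <- pn$nullES[pn$nullES >= 0]
        neg <- pn$nullES[pn$nullES < 0]
        c(if (length(pos) && mean(pos) > 0) pos / mean(pos),
          if (length(neg)) neg / mean(abs(neg)))
    }), use.names = FALSE)
    vapply(seq_len(nrow(res)), function(i) {
        nes <- res$nes[i]
        if (is.na(nes)) return(NA_real_)
        if (nes >= 0) {
            nullTail <- mean(pooled[pooled >= 0] >= nes)
            obs <- res$nes[!is.na(res$nes) & res$nes >= 0]
            obsTail <- mean(obs >= nes)
        } else {
            nullTail <- mean(pooled[pooled < 0] <= nes)
            obs <- res$nes[!is.na(res$nes) & res$nes < 0]
            obsTail <- mean(obs <= nes)
        }
        if (!is.finite(nullTail)) return(NA_real_)
        min(1, nullTail / max(obsTail, .Machine$double.eps))
    }, numeric(1))
}
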