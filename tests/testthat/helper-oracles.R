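# Independent brute-force oracles, deliberately naive implementations.

# Position-by-position running sum for the weighted KS enrichment score.
bruteES <- function(scores, memberNames, w = 1) {
    N <- length(scores)
    hit <- names(scores) %in% memberNames
    Nh <- sum(hit)
    NR <- sum(abs(scores[hit])^w)
    running <- numeric(N)
    cur <- 0
    for (i in seq_len(N)) {
        cur <- if (hit[i]) cur + abs(scores[i])^w / NR
               else cur - 1 / (N - Nh)
        running[i] <- cur
    }
    A <- max(running); B <- min(running)
    # positive extreme wins exact-magnitude ties; the epsilon keeps the
    # naive cumsum from resolving such ties on accumulated rounding noise
    list(es = if (A >= -B - 1e-12) A else B, runningSum = running)
}

# Exhaustive gene-permutation p-value by enumerating every same-size
# subset. A tiny epsilon guards floating-point boundary comparisons of
# equal-by-construction extremes.
bruteExhaustiveP <- function(scores, memberNames, w = 1) {
    esObs <- bruteES(scores, memberNames, w)$es
    N <- length(scores)
    k <- sum(names(scores) %in% memberNames)
    subsets <- utils::combn(N, k)
    nulls <- apply(subsets, 2, function(idx) {
        bruteES(scores, names(scores)[idx], w)$es
    })
    same <- if (esObs >= 0) nulls >= 0 else nulls < 0
    sum(same & abs(nulls) >= abs(esObs) - 1e-12) / max(1, sum(same))
}

# Median-of-ratios size factors computed directly from the definition.
bruteSizeFactors <- function(counts) {
    gm <- apply(counts, 1, function(x) prod(x)^(1 / length(x)))
    keep <- gm > 0
    sapply(seq_len(ncol(counts)), function(j) {
        stats::median(counts[keep, j] / gm[keep])
    })
}

# Benjamini-Hochberg step-up from the definition, returned in input order.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# Hypergeometric upper tail by enumerating all draws of size n.
bruteOraP <- function(universe, marked, drawn) {
    k <- length(intersect(drawn, marked))
    subsets <- utils::combn(length(universe), length(drawn))
    hits <- apply(subsets, 2, function(idx) {
        length(intersect(universe[idx], marked)) >= k
    })
    mean(hits)
}
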