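test_that("singleton sets at the list extremes reach |ES| = 1", {
    ranked <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
    top <- enrichmentScore(ranked, "g1")
    expect_equal(top$es, 1)
    expect_equal(top$peakIndex, 1)
    bottom <- enrichmentScore(ranked, "g5")
    expect_equal(bottom$es, -1)
    expect_equal(bottom$peakIndex, 4)
})

test_that("the running sum matches the brute-force oracle everywhere", {
    ranked <- setNames(10:1, paste0("g", 1:10))
    members <- c("g1", "g4", "g9")
    got <- enrichmentScore(ranked, members, weight = 1)
    oracle <- bruteES(ranked, members, w = 1)
    expect_equal(got$runningSum, oracle$runningSum, tolerance = 1e-12)
    expect_equal(got$es, oracle$es, tolerance = 1e-12)

    set.seed(81)
    for (i in 1:100) {
        N <- sample(5:50, 1)
        ranked <- randomRanked(N)
        k <- sample(seq_len(max(1, N %/% 3)), 1)
        members <- sample(names(ranked), k)
        w <- sample(c(0, 1, 1.5), 1)
        got <- enrichmentScore(ranked, members, weight = w)
        oracle <- bruteES(ranked, members, w = w)
        expect_equal(got$runningSum, oracle$runningSum, tolerance = 1e-9)
        expect_equal(got$es, oracle$es, tolerance = 1e-9)
    }
})

test_that("degenerate member configurations are hard errors", {
    ranked <- setNames(c(2, 1, 0), paste0("g", 1:3))
    expect_error(enrichmentScore(ranked, "absent"), "no gene-set member")
    expect_error(enrichmentScore(ranked, paste0("g", 1:3)), "entire")
    expect_error(enrichmentScore(ranked, "g3", weight = 1), "N_R = 0")
})

test_that("permutation p-values switch to exact enumeration when affordable", {
    ranked <- setNames(c(3.2, 2.1, 1.4, 0.8, -0.5, -1.7), paste0("g", 1:6))
    cfg <- gseaConfig(nPerm = 100, minSize = 1, maxSize = 100, seed = 4)
    pn <- permutationNull(ranked, c("g1", "g2"), cfg)
    expect_true(pn$exact)
    expect_length(pn$nullES, choose(6, 2))
    expect_equal(pn$p, bruteExhaustiveP(ranked, c("g1", "g2")))
    # the most concentrated subset is uniquely extreme among the
    # positive-ES subsets
    expect_equal(pn$p, 1 / sum(pn$nullES >= 0))
})

test_that("sampled permutation p agrees with enumeration in the exact regime", {
    set.seed(83)
    for (i in 1:10) {
        N <- sample(8:12, 1)
        k <- sample(2:3, 1)
        ranked <- randomRanked(N)
        members <- sample(names(ranked), k)
        cfg <- gseaConfig(nPerm = max(100, choose(N, k)), minSize = 1,
                          maxSize = 100, seed = i)
        pn <- permutationNull(ranked, members, cfg)
        expect_true(pn$exact)
        expect_equal(pn$p, bruteExhaustiveP(ranked, members, w = 1))
    }
})

test_that("fixed seeds reproduce sampled permutation p-values", {
    ranked <- randomRanked(200, seed = 5)
    members <- sample(names(ranked), 20)
    cfg <- gseaConfig(nPerm = 200, minSize = 1, maxSize = 500, seed = 99)
    a <- permutationNull(ranked, members, cfg)
    b <- permutationNull(ranked, members, cfg)
    expect_identical(a$p, b$p)
    expect_identical(a$nullES, b$nullES)
    expect_false(a$exact)
})

test_that("reversing the ranked list negates the enrichment score", {
    set.seed(85)
    for (i in 1:20) {
        ranked <- randomRanked(30)
        members <- sample(names(ranked), 5)
        fwd <- enrichmentScore(ranked, members)$es
        # negate scores and flip the order: rank reversal
        revRanked <- -ranked[length(ranked):1]
        rev <- enrichmentScore(revRanked, members)$es
        expect_equal(rev, -fwd, tolerance = 1e-12)
    }
})

test_that("weight 0 ignores score magnitudes entirely", {
    ranked <- randomRanked(40, seed = 6)
    members <- sample(names(ranked), 8)
    es0 <- enrichmentScore(ranked, members, weight = 0)$es
    transformed <- setNames(exp(ranked) + 5, names(ranked))  # monotone
    expect_equal(enrichmentScore(transformed, members, weight = 0)$es, es0)
})

test_that("gseaPreranked filters, ranks and controls FDR coherently", {
    set.seed(87)
    ranked <- randomRanked(300)
    sets <- c(list(everything = names(ranked),
                   tiny = sample(names(ranked), 2)),
              setNames(lapply(1:8, function(i) sample(names(ranked), 25)),
                       paste0("rand", 1:8)))
    gsc <- GeneSetCollection(sets)
    cfg <- gseaConfig(nPerm = 200, minSize = 5, maxSize = 200, seed = 7)
    expect_message(res <- gseaPreranked(ranked, gsc, cfg), "skipped")
    expect_setequal(res$set, paste0("rand", 1:8))
    expect_equal(names(attr(res, "skipped")), c("everything", "tiny"))
    expect_false(is.unsorted(rev(res$nes)))
    # BH is order-equivariant, so the check holds on the sorted table too
    expect_equal(res$fdr, bhAdjust(res$p_perm), tolerance = 1e-12)
    expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
    # leading edge members are set members on the correct side of the peak
    for (i in seq_len(nrow(res))) {
        le <- strsplit(res$leading_edge[i], ";")[[1]]
        expect_true(all(le %in% geneSets(gsc)[[res$set[i]]]))
    }
    expect_error(gseaPreranked(ranked,
                               GeneSetCollection(list(tiny = sets$tiny)),
                               cfg), "filtered out")
})

test_that("enrichment scores agree with fgsea on positive-score lists", {
    set.seed(89)
    ranked <- sort(runif(100, 0.1, 5), decreasing = TRUE)
    names(ranked) <- sprintf("g%03d", sample(100))
    for (i in 1:10) {
        members <- sample(names(ranked), 12)
        mine <- enrichmentScore(ranked, members, weight = 1)$es
        ref <- fgsea::calcGseaStat(unname(ranked),
                                   sort(match(members, names(ranked))),
                                   gseaParam = 1)
        expect_equal(mine, ref, tolerance = 1e-9)
    }
})

test_that("gsea-style pooled FDR is available and bounded", {
    set.seed(91)
    ranked <- randomRanked(200)
    gsc <- GeneSetCollection(setNames(
        lapply(1:6, function(i) sample(names(ranked), 20)),
        paste0("s", 1:6)))
    res <- gseaPreranked(ranked, gsc,
                         gseaConfig(nPerm = 200, minSize = 5, maxSize = 100,
                                    seed = 11, fdrMethod = "gsea_style"))
    expect_true(all(res$fdr >= 0 & res$fdr <= 1, na.rm = TRUE))
})
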