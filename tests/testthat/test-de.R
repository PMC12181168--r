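test_that("paired test degenerate cases follow the t continuity limits", {
    # 50 filler genes, identical in every library, pin all size factors
    # at exactly 1; one flat gene, one exactly-quadrupling gene
    set.seed(21)
    filler <- matrix(rpois(50, 30) + 1L, 50, 1)[, rep(1, 8)]
    flat <- rep(10L, 8)
    up <- rep(c(10L, 40L), 4)
    m <- rbind(filler, flat, up)
    rownames(m) <- c(sprintf("f%02d", 1:50), "flat", "up")
    subj <- sprintf("S%d", 1:4)
    colnames(m) <- as.vector(rbind(paste0(subj, "_pre"),
                                   paste0(subj, "_post")))
    pce <- makeToyExperiment(m, nYoung = 4, nOld = 0)

    de <- pairedDETest(pce, "young", minMeanCount = 0)
    expect_equal(unname(medianOfRatios(m)), rep(1, 8))
    i <- match("flat", de$gene)
    expect_equal(de$log2FC[i], 0)
    expect_equal(de$p[i], 1)
    j <- match("up", de$gene)
    expect_equal(de$log2FC[j], log2(40.5 / 10.5))
    expect_true(is.infinite(de$statistic[j]) && de$statistic[j] > 0)
    expect_equal(de$p[j], 0)
})

test_that("the null rejection rate is calibrated at alpha = 0.05", {
    sim <- simulateCohort(simConfig(nGenes = 800, fracDE = 0,
                                    nPhenoGenes = 0, seed = 19))
    de <- pairedDETest(normalizeCounts(sim$experiment), "old")
    m <- sum(!de$filtered)
    rate <- mean(de$p[!de$filtered] < 0.05)
    half <- 2.576 * sqrt(0.05 * 0.95 / m)
    expect_lt(abs(rate - 0.05), half)
})

test_that("planted effects give power well above the type-I rate", {
    sim <- simulateCohort(simConfig(nGenes = 600, fracDE = 0.1,
                                    lfcMean = 1, nPhenoGenes = 0,
                                    seed = 23))
    de <- pairedDETest(normalizeCounts(sim$experiment), "old")
    tt <- truthSummary(sim$truth, de = de)
    power <- mean(tt$p[tt$isDE & !tt$filtered] < 0.05)
    fpr <- mean(tt$p[!tt$isDE & !tt$filtered] < 0.05)
    expect_gt(power, 0.5)
    expect_gt(power, fpr + 0.3)
})

test_that("small cohorts are rejected", {
    sim <- simulateCohort(simConfig(nYoung = 2, nOld = 3, nGenes = 50,
                                    seed = 1))
    expect_error(pairedDETest(normalizeCounts(sim$experiment), "young"),
                 "at least 3")
})

test_that("bhAdjust reproduces the step-up oracle and validates input", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    set.seed(31)
    for (i in 1:200) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
    }
    # permutation equivariance
    p <- runif(25)
    perm <- sample(25)
    expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(0.5, NA)), "missing")
})

test_that("classification set algebra and percentages are exact", {
    empty <- data.frame(gene = "A", log2FC = 0, p = 1)
    cls <- classifyDE(empty, empty)
    expect_true(all(lengths(cls$sets) == 0))

    young <- data.frame(gene = c("A", "B", "D"), log2FC = c(1, 1, -1),
                        p = c(0.01, 0.01, 0.01))
    old <- data.frame(gene = c("B", "C"), log2FC = c(1, 1), p = c(0.01, 0.01))
    cls <- classifyDE(young, old)
    expect_identical(cls$sets$common_up, "B")
    expect_identical(cls$sets$young_only_up, "A")
    expect_identical(cls$sets$old_only_up, "C")
    expect_identical(cls$sets$young_only_down, "D")
    expect_equal(cls$summary$pct_common_up, 100 / 3)

    expect_error(classifyDE(young, old, alpha = 0), "positive")
})

test_that("cohort significant sets partition into common and unique parts", {
    set.seed(41)
    for (i in 1:20) {
        mk <- function(n) data.frame(
            gene = sample(sprintf("g%02d", 1:40), n),
            log2FC = rnorm(n, 0, 1), p = runif(n)^2)
        y <- mk(30); o <- mk(30)
        cls <- classifyDE(y, o, alpha = 0.2, lfcThreshold = 0.3)
        yUp <- y$gene[y$p < 0.2 & y$log2FC > 0.3]
        expect_setequal(yUp, c(cls$sets$common_up, cls$sets$young_only_up))
        expect_length(intersect(cls$sets$common_up, cls$sets$young_only_up), 0)
        expect_length(intersect(cls$sets$common_up, cls$sets$old_only_up), 0)
    }
})

test_that("overlap fixture tables realise the requested structure", {
    tabs <- makeOverlapDETables(nCommonUp = 3, nYoungOnlyUp = 2,
                                nOldOnlyUp = 4, nCommonDown = 1,
                                nYoungOnlyDown = 5, nOldOnlyDown = 0,
                                nNull = 10)
    cls <- classifyDE(tabs$young, tabs$old)
    s <- cls$summary
    expect_equal(s$n_common_up, 3)
    expect_equal(s$n_young_only_up, 2)
    expect_equal(s$n_old_only_up, 4)
    expect_equal(s$n_common_down, 1)
    expect_equal(s$n_young_only_down, 5)
    expect_equal(s$n_old_only_down, 0)
    expect_equal(nrow(tabs$young), 3 + 2 + 4 + 1 + 5 + 0 + 10)
})

test_that("hypergeometric ORA matches exact enumeration", {
    universe <- sprintf("u%02d", 1:10)
    marked <- universe[1:5]
    drawn <- universe[c(1, 2, 3, 4)]
    gsc <- GeneSetCollection(list(S = marked))
    res <- oraHypergeometric(drawn, universe, gsc)
    expect_equal(res$p, choose(5, 4) * choose(5, 0) / choose(10, 4))
    expect_equal(res$p, bruteOraP(universe, marked, drawn))

    # degenerate cases
    gscEmpty <- GeneSetCollection(list(S = "not_in_universe"))
    res0 <- oraHypergeometric(drawn, universe, gscEmpty, minSize = 0)
    expect_equal(res0$p, 1)
    resAll <- oraHypergeometric(universe, universe, gsc)
    expect_equal(resAll$p, 1)
    expect_error(oraHypergeometric(c(drawn, "zzz"), universe, gsc),
                 "subset")
})

test_that("gene list intersection is exact and case-sensitive", {
    expect_identical(as.character(intersectGeneLists(c("A", "B"), c("B", "C"))),
                     "B")
    expect_equal(attr(intersectGeneLists("A", "B"), "n"), 0)
    expect_identical(as.character(intersectGeneLists("actb", "ACTB")),
                     character(0))
    set.seed(51)
    a <- sample(letters, 10); b <- sample(letters, 10)
    expect_setequal(as.character(intersectGeneLists(a, b)), intersect(a, b))
})
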