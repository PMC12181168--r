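test_that("subject log2 fold-changes follow the prior-count arithmetic", {
    # identical filler columns pin size factors at 1 (normalized == raw)
    filler <- matrix(rpois(30, 25) + 1L, 30, 1)[, rep(1, 6)]
    g1 <- c(10L, 20L, 0L, 3L, 5L, 5L)  # per subject: pre, post alternating
    m <- rbind(filler, g1)
    rownames(m) <- c(sprintf("f%02d", 1:30), "g1")
    subj <- paste0("S", 1:3)
    colnames(m) <- as.vector(rbind(paste0(subj, "_pre"),
                                   paste0(subj, "_post")))
    pce <- makeToyExperiment(m, nYoung = 3, nOld = 0)
    lfc <- subjectLog2FC(pce, prior = 0.5)
    expect_equal(unname(lfc["g1", ]),
                 c(log2(20.5 / 10.5), log2(3.5 / 0.5), 0))
    expect_equal(unname(lfc["g1", 2]), log2(7))
    expect_true(all(lfc[1:30, ] == 0))
})

test_that("swapping pre and post labels negates the fold-change matrix", {
    sim <- simulateCohort(simConfig(nGenes = 60, seed = 13))
    x <- normalizeCounts(sim$experiment)
    lfc <- subjectLog2FC(x)
    swapped <- x
    cd <- SummarizedExperiment::colData(swapped)
    cd$timepoint <- ifelse(cd$timepoint == "pre", "post", "pre")
    SummarizedExperiment::colData(swapped) <- cd
    expect_equal(subjectLog2FC(swapped), -lfc, ignore_attr = TRUE)
})

test_that("pearsonR matches the moment formula and base R", {
    x <- c(1, 2, 3, 5)
    expect_equal(pearsonR(x, x), 1)
    expect_equal(pearsonR(x, -2 * x + 7), -1)
    expect_equal(pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
    expect_true(is.na(pearsonR(x, rep(1, 4))))
    expect_error(pearsonR(x, 1:3), "equal length")
    expect_error(pearsonR(1:2, 1:2), "at least 3")
    set.seed(61)
    for (i in 1:50) {
        a <- rnorm(sample(3:20, 1)); b <- rnorm(length(a))
        expect_equal(pearsonR(a, b), cor(a, b), tolerance = 1e-12)
        # invariance under positive affine maps, antisymmetry under flips
        expect_equal(pearsonR(2 * a + 3, b), pearsonR(a, b))
        expect_equal(pearsonR(-a, b), -pearsonR(a, b))
    }
})

test_that("gene-phenotype correlations recover planted structure", {
    sim <- simulateCohort(simConfig(nGenes = 50, seed = 17))
    x <- normalizeCounts(sim$experiment)
    lfc <- subjectLog2FC(x)
    d <- sim$phenotypes$delta[sim$phenotypes$phenotype == "lean_mass_kg"]
    names(d) <- sim$phenotypes$subject_id[
        sim$phenotypes$phenotype == "lean_mass_kg"]
    # plant a gene whose fold-changes equal the deltas exactly
    lfc <- rbind(lfc, planted = d[colnames(lfc)],
                 constant = rep(1, ncol(lfc)))
    co <- correlateGenes(lfc, sim$phenotypes, "lean_mass_kg")
    expect_equal(co$r[co$gene == "planted"], 1)
    expect_true(is.na(co$r[co$gene == "constant"]))
    expect_true(all(co$n == 18))
    # per-gene values match the scalar implementation
    for (g in sample(rownames(lfc), 5)) {
        expect_equal(co$r[co$gene == g],
                     pearsonR(lfc[g, names(d)], unname(d)))
    }
})

test_that("coupled genes out-correlate null genes across seeds", {
    wins <- 0L
    for (s in 1:20) {
        sim <- simulateCohort(simConfig(nGenes = 120, nPhenoGenes = 25,
                                        rhoTarget = 0.8, seed = 100 + s))
        co <- correlateGenes(subjectLog2FC(normalizeCounts(sim$experiment)),
                             sim$phenotypes, "lean_mass_kg")
        tt <- truthSummary(sim$truth, corr = co)
        if (mean(tt$r[tt$isCoupled], na.rm = TRUE) >
            mean(tt$r[!tt$isCoupled], na.rm = TRUE)) wins <- wins + 1L
    }
    expect_equal(wins, 20L)
})

test_that("subjects without a phenotype delta are dropped pairwise", {
    sim <- simulateCohort(simConfig(nGenes = 40, seed = 29))
    ph <- sim$phenotypes
    ph <- ph[!(ph$subject_id %in% c("Y01", "O03") &
               ph$phenotype == "lean_mass_kg"), ]
    lfc <- subjectLog2FC(normalizeCounts(sim$experiment))
    expect_message(co <- correlateGenes(lfc, ph, "lean_mass_kg"),
                   "2 subject")
    expect_true(all(co$n == 16))
    ph2 <- ph[ph$subject_id %in% c("Y02", "Y03"), ]
    expect_error(correlateGenes(lfc, ph2, "lean_mass_kg"), "fewer than 3")
})

test_that("ranking is descending with deterministic tie-breaks", {
    expect_identical(names(rankBy(data.frame(gene = c("A", "B"),
                                             r = c(0.5, 0.9)), "r")),
                     c("B", "A"))
    tied <- data.frame(gene = c("A", "C", "B"), r = c(0.5, 0.5, 0.9))
    expect_identical(names(rankBy(tied, "r")), c("B", "A", "C"))
    withNa <- data.frame(gene = c("A", "B", "C"), r = c(0.2, NA, 0.7))
    expect_message(rk <- rankBy(withNa, "r"), "1 gene")
    expect_identical(names(rk), c("C", "A"))
    expect_error(rankBy(data.frame(gene = "A", r = NA_real_), "r"),
                 "no genes")
    set.seed(71)
    tab <- data.frame(gene = sprintf("g%03d", sample(100)), r = rnorm(100))
    rk <- rankBy(tab, "r")
    expect_identical(unname(rk), sort(tab$r, decreasing = TRUE))
    expect_identical(names(rk), tab$gene[order(-tab$r, tab$gene)])
})

test_that("ranked lists round-trip through RNK files", {
    set.seed(73)
    rk <- rankBy(data.frame(gene = sprintf("g%02d", 1:20), r = rnorm(20)),
                 "r")
    f <- withr::local_tempfile(fileext = ".rnk")
    writeRnk(rk, f)
    expect_equal(readRnk(f), rk)
})
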