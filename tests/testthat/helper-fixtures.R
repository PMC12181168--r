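# Shared fixture builders; everything is generated in code at test time.

# A minimal valid paired experiment from a genes x samples count matrix.
# Columns must be ordered subject-major (pre, post per subject).
makeToyExperiment <- function(counts, nYoung, nOld) {
    subjects <- c(sprintf("Y%02d", seq_len(nYoung)),
                  sprintf("O%02d", seq_len(nOld)))
    samples <- data.frame(
        sample_id = colnames(counts),
        subject_id = rep(subjects, each = 2),
        cohort = rep(rep(c("young", "old"), c(nYoung, nOld)), each = 2),
        timepoint = rep(c("pre", "post"), nYoung + nOld),
        stringsAsFactors = FALSE)
    PairedCohortExperiment(counts, samples)
}

# Random counts with subject-major pre/post columns.
randomCounts <- function(nGenes, nSubjects, lambda = 50) {
    m <- matrix(rpois(nGenes * 2 * nSubjects, lambda), nGenes)
    rownames(m) <- sprintf("g%03d", seq_len(nGenes))
    subj <- sprintf("S%02d", seq_len(nSubjects))
    colnames(m) <- as.vector(rbind(paste0(subj, "_pre"),
                                   paste0(subj, "_post")))
    m
}

# Random ranked list with distinct scores.
randomRanked <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    s <- sort(rnorm(n), decreasing = TRUE)
    names(s) <- sprintf("g%03d", sample.int(n))
    s
}
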