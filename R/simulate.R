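#' @importFrom stats rnorm rlnorm rnbinom setNames
NULL

#' Ground truth of a simulated cohort
#'
#' @slot geneTruth data.frame (gene, trueLog2FC, isDE, isCoupled).
#' @slot subjectDelta named numeric: the phenotype change each coupled
#'   gene's subject-level log2FC tracks.
#' @slot lfcTarget matrix genes x subjects of the subject-specific true
#'   log2 fold-change targets \eqn{b_{gs}}.
#' @export
setClass("SimulationTruth", representation(
    geneTruth = "data.frame", subjectDelta = "numeric",
    lfcTarget = "matrix"))

setValidity("SimulationTruth", function(object) {
    msg <- character()
    if (nrow(object@geneTruth) != nrow(object@lfcTarget))
        msg <- c(msg, "geneTruth and lfcTarget disagree on gene count")
    if (length(object@subjectDelta) != ncol(object@lfcTarget))
        msg <- c(msg, "subjectDelta and lfcTarget disagree on subject count")
    if (any(object@geneTruth$isCoupled & is.na(object@geneTruth$gene)))
        msg <- c(msg, "coupled genes must be named")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationTruth", function(object) {
    cat(sprintf(
        "SimulationTruth: %d genes (%d DE, %d phenotype-coupled), %d subjects\n",
        nrow(object@geneTruth), sum(object@geneTruth$isDE),
        sum(object@geneTruth$isCoupled), length(object@subjectDelta)))
})

# Baseline (pre-training) phenotype levels used to turn simulated deltas
# into pre/post pairs; values are typical adult male vastus-lateralis
# study magnitudes.
.PHENO_BASELINE_MEAN <- c(lean_mass_kg = 55, leg_extension_Nm = 180,
                          leg_flexion_Nm = 95, type2_csa_um2 = 5200)
.PHENO_BASELINE_SD   <- c(lean_mass_kg = 5, leg_extension_Nm = 35,
                          leg_flexion_Nm = 20, type2_csa_um2 = 900)

#' Simulate a paired pre/post training cohort
#'
#' Draws a synthetic resistance-training study: overdispersed
#' negative-binomial counts for paired muscle biopsies of a young and an
#' older cohort, with a per-subject random effect shared by both
#' timepoints, a planted subset of training-responsive genes, and a
#' planted subset of genes whose subject-level log2 fold-change is
#' correlated with a subject-level phenotype change at a target Pearson
#' correlation.
#'
#' The generative model, in draw order: (1) per-gene baseline means
#' \eqn{\mu_g} log-normal; (2) per-subject random effects
#' \eqn{u_s \sim N(0, \sigma_u)}; (3) per-subject phenotype deltas
#' \eqn{d_s} (per cohort, all four phenotypes; pre values drawn around
#' field-typical baselines); (4) training log2FCs \eqn{\beta_g} for the DE
#' subset; for coupled genes, subject-specific targets
#' \eqn{b_{gs} = \beta_g + \gamma z(d_s) + \epsilon_{gs}} with
#' \eqn{\gamma = \rho\,\tau} and
#' \eqn{sd(\epsilon) = \tau\sqrt{1-\rho^2}} (\eqn{\tau} =
#' \code{couplingSd}, \eqn{z} = standardized delta), so that
#' \eqn{corr(b_{gs}, d_s) = \rho} in expectation; (5) mean counts
#' \eqn{m_{gs,pre} = \mu_g e^{u_s}},
#' \eqn{m_{gs,post} = m_{gs,pre} 2^{b_{gs}}}; (6) per-sample log-normal
#' library scaling; (7) counts
#' \eqn{K \sim NB(m, \phi_g)} with \eqn{\phi_g = a_0/\mu_g + a_1}.
#' The same seed yields bit-identical output.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{PairedCohortExperiment}), \code{phenotypes}
#'   (data.frame as \code{\link{readPhenotypes}}) and \code{truth}
#'   (\linkS4class{SimulationTruth}).
#' @examples
#' sim <- simulateCohort(simConfig(nGenes = 100, nPhenoGenes = 10, seed = 7))
#' sim$truth
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    if (abs(config@rhoTarget) == 1 && config@nPhenoGenes > 0)
        stop("rhoTarget of magnitude 1 is unattainable: the coupling model ",
             "always carries residual noise sd couplingSd*sqrt(1-rho^2); ",
             "use |rhoTarget| < 1")
    set.seed(as.integer(config@seed))

    nG <- as.integer(config@nGenes)
    genes <- sprintf("gene_%05d", seq_len(nG))
    subjects <- c(sprintf("Y%02d", seq_len(config@nYoung)),
                  sprintf("O%02d", seq_len(config@nOld)))
    cohort <- rep(c("young", "old"), c(config@nYoung, config@nOld))
    nS <- length(subjects)

    # (1) baseline means
    mu <- rlnorm(nG, config@baselineLogMean, config@baselineLogSd)
    # (2) subject random effects
    u <- rnorm(nS, 0, config@subjectEffectSd)
    # (3) phenotype pre values and deltas
    ph <- do.call(rbind, lapply(.PHENOTYPES, function(p) {
        pre <- rnorm(nS, .PHENO_BASELINE_MEAN[[p]], .PHENO_BASELINE_SD[[p]])
        mns <- ifelse(cohort == "young",
                      config@phenoDeltaMeanYoung[[p]],
                      config@phenoDeltaMeanOld[[p]])
        sds <- ifelse(cohort == "young",
                      config@phenoDeltaSdYoung[[p]],
                      config@phenoDeltaSdOld[[p]])
        delta <- rnorm(nS, mns, sds)
        data.frame(subject_id = subjects, phenotype = p,
                   pre = pre, post = pre + delta, delta = delta,
                   stringsAsFactors = FALSE)
    }))
    rownames(ph) <- NULL
    d <- ph$delta[ph$phenotype == config@couplePhenotype]
    names(d) <- subjects

    # (4) planted effects
    nDE <- round(config@fracDE * nG)
    deIdx <- if (nDE > 0) sample.int(nG, nDE) else integer()
    beta <- numeric(nG)
    if (nDE > 0) {
        sign <- ifelse(stats::runif(nDE) < config@lfcUpFraction, 1, -1)
        beta[deIdx] <- sign * abs(rnorm(nDE, config@lfcMean, config@lfcSd))
    }
    nCp <- as.integer(config@nPhenoGenes)
    pool <- setdiff(seq_len(nG), deIdx)
    if (nCp > length(pool))
        stop("nPhenoGenes exceeds the number of genes available outside ",
             "the DE subset")
    cpIdx <- if (nCp > 0) sample(pool, nCp) else integer()

    b <- matrix(rep(beta, nS), nG, nS,
                dimnames = list(genes, subjects))
    if (nCp > 0) {
        z <- as.numeric(scale(d))
        gamma <- config@rhoTarget * config@couplingSd
        noiseSd <- config@couplingSd * sqrt(1 - config@rhoTarget^2)
        eps <- matrix(rnorm(nCp * nS, 0, noiseSd), nCp, nS)
        b[cpIdx, ] <- b[cpIdx, ] + rep(gamma * z, each = nCp) + eps
    }

    # (5) timepoint means, (6) library scaling, (7) NB counts
    mPre <- outer(mu, exp(u))
    mPost <- mPre * 2^b
    lib <- rlnorm(2L * nS, config@libSizeMeanlog, config@libSizeSdlog)
    phi <- config@dispA0 / mu + config@dispA1
    m <- cbind(mPre, mPost)  # pre block then post block, subject order
    m <- sweep(m, 2L, lib, `*`)
    counts <- matrix(rnbinom(length(m), mu = m, size = rep(1 / phi, 2L * nS)),
                     nrow = nG)
    sampleIds <- c(paste0(subjects, "_pre"), paste0(subjects, "_post"))
    dimnames(counts) <- list(genes, sampleIds)
    # interleave per subject: pre, post
    ord <- as.vector(rbind(seq_len(nS), nS + seq_len(nS)))
    counts <- counts[, ord, drop = FALSE]

    samples <- data.frame(
        sample_id = colnames(counts),
        subject_id = rep(subjects, each = 2L),
        cohort = rep(cohort, each = 2L),
        timepoint = rep(c("pre", "post"), nS),
        stringsAsFactors = FALSE)

    truth <- new("SimulationTruth",
                 geneTruth = data.frame(
                     gene = genes, trueLog2FC = beta,
                     isDE = seq_len(nG) %in% deIdx,
                     isCoupled = seq_len(nG) %in% cpIdx,
                     stringsAsFactors = FALSE),
                 subjectDelta = d, lfcTarget = b)

    list(experiment = PairedCohortExperiment(counts, samples),
         phenotypes = ph[c("subject_id", "phenotype", "pre", "post",
                           "delta")],
         truth = truth)
}

#' Join simulation truth to downstream result tables
#'
#' Left-joins the per-gene truth labels to any table keyed by \code{gene}
#' (DE results, correlation tables), preserving the truth's row count, for
#' recovery scoring.
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param ... optional data.frames with a \code{gene} column; their
#'   non-gene columns are suffixed by argument name when names clash.
#' @return data.frame with one row per simulated gene.
#' @export
truthSummary <- function(truth, ...) {
    stopifnot(is(truth, "SimulationTruth"))
    out <- truth@geneTruth
    extras <- list(...)
    for (i in seq_along(extras)) {
        tab <- as.data.frame(extras[[i]])
        if (!"gene" %in% colnames(tab))
            stop("joined tables must have a 'gene' column")
        clash <- intersect(setdiff(colnames(tab), "gene"), colnames(out))
        if (length(clash)) {
            nm <- names(extras)[i]
            suff <- if (!is.null(nm) && nzchar(nm)) nm else as.character(i)
            colnames(tab)[colnames(tab) %in% clash] <-
                paste(clash, suff, sep = ".")
        }
        out <- merge(out, tab, by = "gene", all.x = TRUE, sort = FALSE)
    }
    out[match(truth@geneTruth$gene, out$gene), , drop = FALSE]
}
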