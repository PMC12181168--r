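#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

.COHORTS    <- c("young", "old")
.TIMEPOINTS <- c("pre", "post")
.PHENOTYPES <- c("lean_mass_kg", "leg_extension_Nm", "leg_flexion_Nm",
                 "type2_csa_um2")

#' Paired pre/post cohort experiment
#'
#' A \linkS4class{SummarizedExperiment} of raw gene-level counts whose
#' columns are muscle biopsy samples taken before and after a training
#' intervention. The column data must carry \code{subject_id},
#' \code{cohort} (\code{young}/\code{old}) and \code{timepoint}
#' (\code{pre}/\code{post}); validity enforces that every subject has
#' exactly one pre and one post sample and belongs to a single cohort,
#' and that the \code{counts} assay holds non-negative integers.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("PairedCohortExperiment", contains = "SummarizedExperiment")

.validPairedCohort <- function(object) {
    msg <- character()
    cd <- colData(object)
    need <- c("subject_id", "cohort", "timepoint")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("colData lacks columns:", paste(miss, collapse = ", ")))
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample (column) names must be present and unique")
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "an assay named 'counts' is required")
    else {
        k <- assay(object, "counts")
        if (any(k < 0)) msg <- c(msg, "counts contain negative values")
        if (any(k != round(k))) msg <- c(msg, "counts are not integral")
        if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
            msg <- c(msg, "gene (row) names must be present and unique")
    }
    if (!all(cd$cohort %in% .COHORTS))
        msg <- c(msg, "cohort must be 'young' or 'old'")
    if (!all(cd$timepoint %in% .TIMEPOINTS))
        msg <- c(msg, "timepoint must be 'pre' or 'post'")
    if (!length(msg)) {
        for (s in unique(cd$subject_id)) {
            tp <- cd$timepoint[cd$subject_id == s]
            if (!(sum(tp == "pre") == 1L && sum(tp == "post") == 1L))
                msg <- c(msg, sprintf(
                    "subject '%s' must have exactly one pre and one post sample", s))
            if (length(unique(cd$cohort[cd$subject_id == s])) != 1L)
                msg <- c(msg, sprintf("subject '%s' spans multiple cohorts", s))
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("PairedCohortExperiment", .validPairedCohort)

#' Construct a PairedCohortExperiment
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param sampleData data.frame with columns \code{sample_id},
#'   \code{subject_id}, \code{cohort}, \code{timepoint}; rows are matched to
#'   the columns of \code{counts} by \code{sample_id}.
#' @return A \linkS4class{PairedCohortExperiment}.
#' @examples
#' sim <- simulateCohort(simConfig(nGenes = 50, seed = 1))
#' sim$experiment
#' @export
PairedCohortExperiment <- function(counts, sampleData) {
    sampleData <- as.data.frame(sampleData)
    if (!"sample_id" %in% colnames(sampleData))
        stop("sampleData must have a 'sample_id' column")
    if (anyDuplicated(sampleData$sample_id))
        stop("duplicated sample_id in sampleData")
    if (!setequal(colnames(counts), sampleData$sample_id))
        stop("count matrix columns and sampleData sample_id sets differ")
    sampleData <- sampleData[match(colnames(counts), sampleData$sample_id), ,
                             drop = FALSE]
    cd <- DataFrame(sampleData[setdiff(colnames(sampleData), "sample_id")],
                    row.names = sampleData$sample_id)
    se <- SummarizedExperiment(assays = list(counts = as.matrix(counts)),
                               colData = cd)
    new("PairedCohortExperiment", se)
}

setMethod("show", "PairedCohortExperiment", function(object) {
    cd <- colData(object)
    cat(sprintf(
        "PairedCohortExperiment: %d genes x %d samples (%d subjects: %d young, %d old)\n",
        nrow(object), ncol(object), length(unique(cd$subject_id)),
        length(unique(cd$subject_id[cd$cohort == "young"])),
        length(unique(cd$subject_id[cd$cohort == "old"]))))
    cat("assays:", paste(names(assays(object)), collapse = ", "), "\n")
})

#' Collection of named gene sets
#'
#' A light container for GMT-style gene set collections: a named list of
#' unique member identifiers plus an optional description per set. Members
#' are deduplicated on construction; gene identifiers are opaque,
#' case-sensitive strings.
#'
#' @slot sets named list of character vectors (deduplicated members).
#' @slot descriptions named character vector, parallel to \code{sets}.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
            msg <- c(msg, "set names must be present and unique")
        if (!all(vapply(object@sets, is.character, logical(1))))
            msg <- c(msg, "set members must be character vectors")
        if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0))
            msg <- c(msg, "set members must be deduplicated")
    }
    if (!identical(names(object@descriptions), names(object@sets)))
        msg <- c(msg, "descriptions must be named in parallel with sets")
    if (length(msg)) msg else TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets named list of character vectors.
#' @param descriptions optional named character vector of set descriptions.
#' @return A \linkS4class{GeneSetCollection}.
#' @examples
#' gsc <- GeneSetCollection(list(ecm = c("COL1A1", "LUM"), heme = c("HBB")))
#' geneSets(gsc)
#' @export
GeneSetCollection <- function(sets = list(), descriptions = NULL) {
    sets <- lapply(sets, function(x) unique(as.character(x)))
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(sets)), names(sets))
    else
        descriptions <- descriptions[names(sets)]
    new("GeneSetCollection", sets = sets,
        descriptions = setNames(as.character(descriptions), names(sets)))
}

#' @describeIn GeneSetCollection-class number of sets.
#' @param x a GeneSetCollection.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class set names.
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection of %d sets", length(object)))
    if (length(object)) {
        sz <- lengths(object@sets)
        cat(sprintf(" (sizes %d-%d, median %g)", min(sz), max(sz),
                    stats::median(sz)))
    }
    cat("\n")
})

#' Accessors for gene set collections
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @return \code{geneSets} returns the named list of member vectors;
#'   \code{setDescriptions} the named description vector.
#' @export
geneSets <- function(x) x@sets

#' @rdname geneSets
#' @export
setDescriptions <- function(x) x@descriptions

#' Simulation configuration for a paired training cohort
#'
#' Full statistical description of the synthetic cohort drawn by
#' \code{\link{simulateCohort}}: cohort sizes, the log-normal baseline
#' expression distribution, the negative-binomial mean-dispersion trend
#' \eqn{\phi_g = a_0/\mu_g + a_1}, a per-subject random effect shared by
#' both timepoints, the planted training effect (fraction of genes,
#' log2 fold-change distribution and sign mix), the planted
#' phenotype-coupled genes with a target Pearson correlation, per-cohort
#' phenotype-change distributions, and log-normal library-size variation.
#'
#' @export
setClass("SimConfig", representation(
    nYoung = "numeric", nOld = "numeric", nGenes = "numeric",
    baselineLogMean = "numeric", baselineLogSd = "numeric",
    dispA0 = "numeric", dispA1 = "numeric",
    subjectEffectSd = "numeric",
    fracDE = "numeric", lfcMean = "numeric", lfcSd = "numeric",
    lfcUpFraction = "numeric",
    nPhenoGenes = "numeric", rhoTarget = "numeric", couplingSd = "numeric",
    couplePhenotype = "character",
    phenoDeltaMeanYoung = "numeric", phenoDeltaSdYoung = "numeric",
    phenoDeltaMeanOld = "numeric", phenoDeltaSdOld = "numeric",
    libSizeMeanlog = "numeric", libSizeSdlog = "numeric",
    seed = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nYoung < 1 || object@nOld < 1 || object@nGenes < 1)
        msg <- c(msg, "cohort and gene counts must be positive")
    if (object@fracDE < 0 || object@fracDE > 1)
        msg <- c(msg, "fracDE must lie in [0, 1]")
    if (abs(object@rhoTarget) > 1)
        msg <- c(msg, "|rhoTarget| must not exceed 1")
    if (object@nPhenoGenes > object@nGenes)
        msg <- c(msg, "nPhenoGenes exceeds nGenes")
    if (object@dispA0 < 0 || object@dispA1 < 0)
        msg <- c(msg, "dispersion trend parameters must be non-negative")
    if (object@couplingSd < 0 || object@subjectEffectSd < 0 ||
        object@libSizeSdlog < 0)
        msg <- c(msg, "standard deviations must be non-negative")
    if (!object@couplePhenotype %in% .PHENOTYPES)
        msg <- c(msg, paste("couplePhenotype must be one of:",
                            paste(.PHENOTYPES, collapse = ", ")))
    ok <- function(v) length(v) == length(.PHENOTYPES) &&
        identical(names(v), .PHENOTYPES)
    if (!ok(object@phenoDeltaMeanYoung) || !ok(object@phenoDeltaSdYoung) ||
        !ok(object@phenoDeltaMeanOld) || !ok(object@phenoDeltaSdOld))
        msg <- c(msg, "phenotype delta parameters must be named over the four phenotypes")
    if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#'
#' @param nYoung,nOld subjects per cohort; defaults mirror an 8 young +
#'   10 old resistance-training study.
#' @param nGenes number of genes to simulate.
#' @param baselineLogMean,baselineLogSd natural-log mean and sd of the
#'   per-gene baseline expression (log-normal).
#' @param dispA0,dispA1 negative-binomial dispersion trend
#'   \eqn{\phi_g = a_0/\mu_g + a_1}.
#' @param subjectEffectSd sd of the per-subject log-scale random effect,
#'   applied identically to both timepoints.
#' @param fracDE fraction of genes given a training effect.
#' @param lfcMean,lfcSd,lfcUpFraction magnitude distribution and sign mix
#'   of true training log2 fold-changes.
#' @param nPhenoGenes number of genes whose subject-level log2FC is coupled
#'   to the phenotype change.
#' @param rhoTarget target Pearson correlation for coupled genes
#'   (strictly inside (-1, 1); an exact +/-1 is unattainable with residual
#'   noise).
#' @param couplingSd total sd of the subject-level log2FC variation of a
#'   coupled gene; the coupling slope and residual noise are solved from
#'   \code{rhoTarget} in closed form.
#' @param couplePhenotype which phenotype the coupled genes track.
#' @param phenoDeltaMeanYoung,phenoDeltaSdYoung,phenoDeltaMeanOld,phenoDeltaSdOld
#'   named numeric vectors over the four phenotypes giving the per-cohort
#'   post-minus-pre change distributions (kg, Nm, Nm, um^2).
#' @param libSizeMeanlog,libSizeSdlog log-normal library-size scaling.
#' @param seed integer seed; all draws flow from it in documented order.
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nYoung = 8, nOld = 10, nGenes = 2000,
                      baselineLogMean = 4, baselineLogSd = 1.5,
                      dispA0 = 3, dispA1 = 0.1,
                      subjectEffectSd = 0.2,
                      fracDE = 0.1, lfcMean = 1, lfcSd = 0.25,
                      lfcUpFraction = 0.75,
                      nPhenoGenes = 0, rhoTarget = 0.8, couplingSd = 0.5,
                      couplePhenotype = "lean_mass_kg",
                      phenoDeltaMeanYoung = c(lean_mass_kg = 0.8,
                                              leg_extension_Nm = 30,
                                              leg_flexion_Nm = 15,
                                              type2_csa_um2 = 900),
                      phenoDeltaSdYoung = c(lean_mass_kg = 1.2,
                                            leg_extension_Nm = 15,
                                            leg_flexion_Nm = 8,
                                            type2_csa_um2 = 700),
                      phenoDeltaMeanOld = c(lean_mass_kg = 1.5,
                                            leg_extension_Nm = 22,
                                            leg_flexion_Nm = 11,
                                            type2_csa_um2 = 400),
                      phenoDeltaSdOld = c(lean_mass_kg = 1.3,
                                          leg_extension_Nm = 14,
                                          leg_flexion_Nm = 7,
                                          type2_csa_um2 = 650),
                      libSizeMeanlog = 0, libSizeSdlog = 0.3,
                      seed = 1) {
    new("SimConfig", nYoung = nYoung, nOld = nOld, nGenes = nGenes,
        baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
        dispA0 = dispA0, dispA1 = dispA1,
        subjectEffectSd = subjectEffectSd,
        fracDE = fracDE, lfcMean = lfcMean, lfcSd = lfcSd,
        lfcUpFraction = lfcUpFraction,
        nPhenoGenes = nPhenoGenes, rhoTarget = rhoTarget,
        couplingSd = couplingSd, couplePhenotype = couplePhenotype,
        phenoDeltaMeanYoung = phenoDeltaMeanYoung[.PHENOTYPES],
        phenoDeltaSdYoung = phenoDeltaSdYoung[.PHENOTYPES],
        phenoDeltaMeanOld = phenoDeltaMeanOld[.PHENOTYPES],
        phenoDeltaSdOld = phenoDeltaSdOld[.PHENOTYPES],
        libSizeMeanlog = libSizeMeanlog, libSizeSdlog = libSizeSdlog,
        seed = seed)
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d genes, %d young + %d old subjects; fracDE=%.3g, %d coupled genes (rho=%.2f on %s), seed=%d\n",
        object@nGenes, object@nYoung, object@nOld, object@fracDE,
        object@nPhenoGenes, object@rhoTarget, object@couplePhenotype,
        as.integer(object@seed)))
})

#' Pre-ranked GSEA configuration
#'
#' @slot weight running-sum weight exponent (1 = weighted statistic,
#'   0 = classic Kolmogorov-Smirnov).
#' @slot nPerm number of gene-label permutations (exact enumeration is
#'   substituted whenever the number of same-size subsets does not exceed
#'   it).
#' @slot minSize,maxSize gene-set size filter, applied after restricting a
#'   set to the ranked list.
#' @slot seed integer seed for the permutation stream.
#' @slot fdrMethod \code{"bh_on_perm_p"} (Benjamini-Hochberg across sets,
#'   default) or \code{"gsea_style"} (sign-matched pooled-null NES FDR).
#' @export
setClass("GseaConfig", representation(
    weight = "numeric", nPerm = "numeric", minSize = "numeric",
    maxSize = "numeric", seed = "numeric", fdrMethod = "character"))

setValidity("GseaConfig", function(object) {
    msg <- character()
    if (object@weight < 0) msg <- c(msg, "weight must be >= 0")
    if (object@nPerm < 100) msg <- c(msg, "nPerm must be >= 100")
    if (object@minSize < 1 || object@maxSize < object@minSize)
        msg <- c(msg, "need 0 < minSize <= maxSize")
    if (!object@fdrMethod %in% c("bh_on_perm_p", "gsea_style"))
        msg <- c(msg, "fdrMethod must be 'bh_on_perm_p' or 'gsea_style'")
    if (length(msg)) msg else TRUE
})

#' @rdname GseaConfig-class
#' @param weight,nPerm,minSize,maxSize,seed,fdrMethod see slot documentation.
#' @return A validated \linkS4class{GseaConfig}.
#' @export
gseaConfig <- function(weight = 1, nPerm = 1000, minSize = 15, maxSize = 500,
                       seed = 1, fdrMethod = c("bh_on_perm_p", "gsea_style")) {
    new("GseaConfig", weight = weight, nPerm = nPerm, minSize = minSize,
        maxSize = maxSize, seed = seed, fdrMethod = match.arg(fdrMethod))
}

setMethod("show", "GseaConfig", function(object) {
    cat(sprintf(
        "GseaConfig: weight=%g, nPerm=%d, size filter [%g, %g], seed=%d, fdr=%s\n",
        object@weight, as.integer(object@nPerm), object@minSize,
        object@maxSize, as.integer(object@seed), object@fdrMethod))
})
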