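#' @importFrom tools md5sum
#' @importFrom jsonlite write_json
#' @importFrom utils packageVersion
NULL

#' Assemble and validate a pipeline configuration
#'
#' The full analysis is driven by one configuration: either file paths to
#' the four inputs (counts, samples, phenotypes, GMT) or a simulation
#' block, never both; thresholds for the DE arm; the prior count and
#' cohort scope for the correlation arm; and the GSEA settings.
#'
#' @param counts,samples,phenotypes,gmt input file paths (all four
#'   required unless \code{simulation} is given).
#' @param simulation a \linkS4class{SimConfig}, or NULL.
#' @param outDir output directory.
#' @param alpha,lfcThreshold DE thresholds (unadjusted p and absolute
#'   log2FC).
#' @param thresholdMode \code{"p_and_lfc"} (default) or \code{"p_only"}
#'   for per-cohort significance totals.
#' @param prior pseudo-count for log-scale fold-changes.
#' @param scope correlation cohort scope (\code{"combined"} pools both
#'   cohorts, the default).
#' @param gsea a \linkS4class{GseaConfig}.
#' @param minMeanCount DE expression filter.
#' @param oraMinSize,oraMaxSize ORA set-size filter.
#' @return validated configuration list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(counts = NULL, samples = NULL, phenotypes = NULL,
                           gmt = NULL, simulation = NULL,
                           outDir = tempfile("phenorank_"),
                           alpha = 0.05, lfcThreshold = 0.4,
                           thresholdMode = c("p_and_lfc", "p_only"),
                           prior = 0.5,
                           scope = c("combined", "young", "old"),
                           gsea = gseaConfig(),
                           minMeanCount = 5,
                           oraMinSize = 2, oraMaxSize = Inf) {
    thresholdMode <- match.arg(thresholdMode)
    scope <- match.arg(scope)
    paths <- list(counts = counts, samples = samples,
                  phenotypes = phenotypes, gmt = gmt)
    havePaths <- !vapply(paths, is.null, logical(1))
    if (is.null(simulation)) {
        miss <- names(paths)[!havePaths]
        if (length(miss))
            stop("config lacks input path(s): ", paste(miss, collapse = ", "),
                 " (or provide a simulation block)")
    } else {
        if (any(havePaths[c("counts", "samples", "phenotypes")]))
            stop("provide either input paths or a simulation block, not both")
        stopifnot(is(simulation, "SimConfig"))
    }
    if (alpha <= 0 || lfcThreshold <= 0)
        stop("alpha and lfcThreshold must be positive")
    stopifnot(is(gsea, "GseaConfig"), prior > 0)
    structure(list(paths = paths, simulation = simulation, outDir = outDir,
                   alpha = alpha, lfcThreshold = lfcThreshold,
                   thresholdMode = thresholdMode, prior = prior,
                   scope = scope, gsea = gsea,
                   minMeanCount = minMeanCount,
                   oraMinSize = oraMinSize, oraMaxSize = oraMaxSize),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Mirrors \code{\link{pipelineConfig}}: top-level keys \code{paths}
#' (counts/samples/phenotypes/gmt), or \code{simulation} (fields of
#' \code{\link{simConfig}}), plus \code{de} (alpha, lfc_threshold,
#' threshold_mode, min_mean_count), \code{correlation} (prior, scope) and
#' \code{gsea} (weight, n_perm, min_size, max_size, seed, fdr_method).
#'
#' @param path YAML file.
#' @param outDir output directory override (falls back to the YAML
#'   \code{out_dir}, then a tempdir).
#' @return a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path, outDir = NULL) {
    y <- yaml::read_yaml(path)
    simulation <- if (!is.null(y$simulation))
        do.call(simConfig, y$simulation)
    de <- y$de %||% list()
    corr <- y$correlation %||% list()
    gs <- y$gsea %||% list()
    gsArgs <- list(weight = gs$weight %||% 1, nPerm = gs$n_perm %||% 1000,
                   minSize = gs$min_size %||% 15,
                   maxSize = gs$max_size %||% 500,
                   seed = gs$seed %||% 1,
                   fdrMethod = gs$fdr_method %||% "bh_on_perm_p")
    pipelineConfig(
        counts = y$paths$counts, samples = y$paths$samples,
        phenotypes = y$paths$phenotypes, gmt = y$paths$gmt,
        simulation = simulation,
        outDir = outDir %||% y$out_dir %||% tempfile("phenorank_"),
        alpha = de$alpha %||% 0.05,
        lfcThreshold = de$lfc_threshold %||% 0.4,
        thresholdMode = de$threshold_mode %||% "p_and_lfc",
        prior = corr$prior %||% 0.5,
        scope = corr$scope %||% "combined",
        gsea = do.call(gseaConfig, gsArgs),
        minMeanCount = de$min_mean_count %||% 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.loadInputs <- function(config) {
    if (!is.null(config$simulation)) {
        sim <- simulateCohort(config$simulation)
        gmt <- if (!is.null(config$paths$gmt)) readGmt(config$paths$gmt)
        list(experiment = sim$experiment, phenotypes = sim$phenotypes,
             collection = gmt, truth = sim$truth)
    } else {
        counts <- readCounts(config$paths$counts)
        samples <- readSampleTable(config$paths$samples)
        list(experiment = PairedCohortExperiment(counts, samples),
             phenotypes = readPhenotypes(config$paths$phenotypes),
             collection = readGmt(config$paths$gmt), truth = NULL)
    }
}

#' Run the differential-expression arm
#'
#' Per-cohort paired DE, two-cohort overlap classification at the
#' configured thresholds, and hypergeometric over-representation of each
#' of the six classified sets against the supplied collection. All tables
#' are written as TSV under \code{<outDir>/de}.
#'
#' @param experiment a \linkS4class{PairedCohortExperiment}.
#' @param collection a \linkS4class{GeneSetCollection} (or NULL to skip
#'   ORA).
#' @param config a \code{PipelineConfig} supplying thresholds, prior and
#'   filters.
#' @return list with \code{deYoung}, \code{deOld}, \code{classification},
#'   \code{ora} (named list over the six sets), \code{files}.
#' @export
runDEArm <- function(experiment, collection, config = pipelineConfig(
                         simulation = simConfig())) {
    experiment <- .normalizedAssay(experiment)
    deY <- pairedDETest(experiment, "young", prior = config$prior,
                        minMeanCount = config$minMeanCount)
    deO <- pairedDETest(experiment, "old", prior = config$prior,
                        minMeanCount = config$minMeanCount)
    cls <- classifyDE(deY, deO, alpha = config$alpha,
                      lfcThreshold = config$lfcThreshold)
    message(sprintf(
        "DE arm: %d/%d genes tested (young/old); young %d sig, old %d sig [%s mode]",
        sum(!deY$filtered), sum(!deO$filtered),
        countSignificant(deY, config$alpha,
                         if (config$thresholdMode == "p_and_lfc")
                             config$lfcThreshold),
        countSignificant(deO, config$alpha,
                         if (config$thresholdMode == "p_and_lfc")
                             config$lfcThreshold),
        config$thresholdMode))
    universe <- deY$gene[!deY$filtered | !deO$filtered]
    ora <- NULL
    if (!is.null(collection) && length(collection)) {
        ora <- lapply(cls$sets, function(s)
            oraHypergeometric(intersect(s, universe), universe, collection,
                              minSize = config$oraMinSize,
                              maxSize = config$oraMaxSize))
    }
    dir <- file.path(config$outDir, "de")
    tables <- c(list(de_young = deY, de_old = deO,
                     classification_summary = cls$summary,
                     classification_sets = data.frame(
                         set = rep(names(cls$sets), lengths(cls$sets)),
                         gene = unlist(cls$sets, use.names = FALSE))),
                if (!is.null(ora))
                    setNames(ora, paste0("ora_", names(ora))))
    files <- writeResults(tables, dir)
    list(deYoung = deY, deOld = deO, classification = cls, ora = ora,
         files = files)
}

#' Run the phenotype-correlation arm
#'
#' The subject-specific chain for one phenotype: per-subject log2
#' fold-changes, per-gene Pearson correlation with the phenotype change,
#' deterministic ranking by r, and pre-ranked GSEA. Intermediates (the
#' correlation table, the RNK ranked list, the enrichment table) are
#' written under \code{<outDir>/correlation_<phenotype>}.
#'
#' @param experiment a \linkS4class{PairedCohortExperiment}.
#' @param phenotypes phenotype table (see \code{\link{readPhenotypes}}).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param phenotype phenotype label to correlate against.
#' @param config a \code{PipelineConfig}.
#' @return list with \code{lfc}, \code{correlation}, \code{ranked},
#'   \code{enrichment}, \code{files}.
#' @export
runCorrelationArm <- function(experiment, phenotypes, collection, phenotype,
                              config = pipelineConfig(
                                  simulation = simConfig())) {
    if (!phenotype %in% phenotypes$phenotype)
        stop("phenotype '", phenotype, "' absent from the phenotype table")
    experiment <- .normalizedAssay(experiment)
    lfc <- subjectLog2FC(experiment, prior = config$prior,
                         scope = config$scope)
    corr <- correlateGenes(lfc, phenotypes, phenotype)
    ranked <- rankBy(corr, "r")
    enr <- gseaPreranked(ranked, collection, config$gsea)
    message(sprintf(
        "correlation arm [%s]: %d genes ranked over %d subjects; %d sets tested, %d at fdr < 0.05",
        phenotype, length(ranked), corr$n[1], nrow(enr),
        sum(enr$fdr < 0.05, na.rm = TRUE)))
    dir <- file.path(config$outDir, paste0("correlation_", phenotype))
    files <- writeResults(list(correlation = corr,
                               enrichment = enr), dir)
    rnk <- file.path(dir, "ranked.rnk")
    writeRnk(ranked, rnk)
    list(lfc = lfc, correlation = corr, ranked = ranked, enrichment = enr,
         files = c(files, rnk))
}

#' Run the full analysis
#'
#' Executes the DE arm and the correlation arm for all four phenotypes
#' from a configuration (file paths or simulation), then writes a JSON
#' manifest recording input hashes, seeds, package and R versions, and
#' every output path with its MD5, so identical configurations are
#' auditable down to bytes.
#'
#' @param config a \code{PipelineConfig}.
#' @return invisibly, the manifest list (also written to
#'   \code{<outDir>/manifest.json}).
#' @export
runAll <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    inp <- .loadInputs(config)
    if (is.null(inp$collection) || !length(inp$collection))
        stop("runAll requires a gene set collection (gmt path)")
    if (!dir.exists(config$outDir))
        dir.create(config$outDir, recursive = TRUE)
    de <- runDEArm(inp$experiment, inp$collection, config)
    arms <- list()
    for (ph in .PHENOTYPES) {
        arms[[ph]] <- runCorrelationArm(inp$experiment, inp$phenotypes,
                                        inp$collection, ph, config)
    }
    outputs <- c(unlist(de$files, use.names = FALSE),
                 unlist(lapply(arms, `[[`, "files"), use.names = FALSE))
    inputHashes <- if (is.null(config$simulation)) {
        as.list(md5sum(unlist(config$paths, use.names = TRUE)))
    } else {
        list(simulation_seed = as.integer(config$simulation@seed),
             gmt = unname(md5sum(config$paths$gmt)))
    }
    manifest <- list(
        package = "phenorank",
        version = as.character(packageVersion("phenorank")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        inputs = inputHashes,
        seeds = list(gsea = as.integer(config$gsea@seed),
                     simulation = if (!is.null(config$simulation))
                         as.integer(config$simulation@seed)),
        thresholds = list(alpha = config$alpha,
                          lfc = config$lfcThreshold,
                          mode = config$thresholdMode,
                          prior = config$prior),
        arms = c("de", paste0("correlation_", .PHENOTYPES)),
        outputs = as.list(md5sum(sort(outputs))))
    write_json(manifest, file.path(config$outDir, "manifest.json"),
               auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
    invisible(manifest)
}
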