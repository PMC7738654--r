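#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]. Exactly
#' one input route must be given: real data (`rccDir` or `countsTsv`, with
#' a `sampleSheet`) or a simulation block (`simulate`, a [simConfig()]).
#'
#' @param rccDir directory of RCC files (one per lane).
#' @param countsTsv plain TSV count matrix (see [readCountsTsv()]).
#' @param sampleSheet two-column TSV or data.frame (`sample_id`, `group`).
#' @param simulate a [simConfig()]; mutually exclusive with file inputs.
#' @param gmtFiles character vector of GMT paths for enrichment (optional;
#'   the bundled toy collection is used when omitted so the stage is
#'   exercised end to end).
#' @param hkScreenK background multiple for housekeeping screening.
#' @param snrCutoff,snrMinFraction,snrScope detection-rule parameters, see
#'   [scoreDetection()].
#' @param hkSelection `"correlation"` (panel by pairwise r, used for DE
#'   normalization) or `"genorm"` (most stable genes by geNorm ranking,
#'   used for the all-gene heatmap).
#' @param hkPanelSize,hkMinR panel-selection parameters.
#' @param tVariant,fcCutoff,alpha,correction,fcMode DE-stage parameters.
#' @param linkage clustering linkage.
#' @param seed integer seed controlling all randomness.
#' @return a validated `pipelineConfig` list.
#' @export
pipelineConfig <- function(rccDir = NULL, countsTsv = NULL,
                           sampleSheet = NULL, simulate = NULL,
                           gmtFiles = NULL,
                           hkScreenK = 3, snrCutoff = 3,
                           snrMinFraction = 0.5,
                           snrScope = "any_group",
                           hkSelection = c("correlation", "genorm"),
                           hkPanelSize = 4L, hkMinR = 0.8,
                           tVariant = "student", fcCutoff = 1.5,
                           alpha = 0.05, correction = "none",
                           fcMode = "log2_means",
                           linkage = "average", seed = 1L) {
    hkSelection <- match.arg(hkSelection)
    hasFiles <- !is.null(rccDir) || !is.null(countsTsv)
    if (hasFiles == !is.null(simulate))
        stop("exactly one of file inputs (rccDir/countsTsv) or a simulate ",
             "block must be given")
    if (hasFiles && is.null(sampleSheet))
        stop("file inputs require a sampleSheet")
    if (!is.null(simulate) && !inherits(simulate, "simConfig"))
        stop("simulate must be a simConfig()")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    cfg <- list(rccDir = rccDir, countsTsv = countsTsv,
                sampleSheet = sampleSheet, simulate = simulate,
                gmtFiles = gmtFiles, hkScreenK = hkScreenK,
                snrCutoff = snrCutoff, snrMinFraction = snrMinFraction,
                snrScope = snrScope, hkSelection = hkSelection,
                hkPanelSize = as.integer(hkPanelSize), hkMinR = hkMinR,
                tVariant = tVariant, fcCutoff = fcCutoff, alpha = alpha,
                correction = correction, fcMode = fcMode, linkage = linkage,
                seed = as.integer(seed))
    class(cfg) <- c("pipelineConfig", "list")
    cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param file YAML path; keys as in [pipelineConfig()], with `simulate` as
#'   a nested map of [simConfig()] arguments.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(file) {
    y <- yaml::read_yaml(file)
    if (!is.null(y$simulate)) y$simulate <- do.call(simConfig, y$simulate)
    do.call(pipelineConfig, y)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> background -> housekeeping QC -> normalize ->
#' detect -> differential expression -> enrichment -> clustering/volcano,
#' writing every intermediate table plus a JSON run manifest (stage counts,
#' configuration echo, seed). Identical configuration and seed give an
#' identical manifest.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory (created; default tempdir subdir).
#' @return the manifest, invisibly a list with entries `counts` (named
#'   per-stage numbers), `outdir`, and the key result objects (`object`,
#'   `de`, `enrichmentUp`, `enrichmentDown`, `cluster`).
#' @export
runPipeline <- function(config, outdir = file.path(tempdir(), "ncounter_run")) {
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(outdir, "pipeline.log")
    logln <- function(...) cat(..., "\n", sep = "", file = log, append = TRUE)
    cat("", file = log)
    stage <- function(name, expr) {
        logln("[", name, "] start")
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    truth <- NULL
    obj <- stage("input", {
        if (!is.null(config$simulate)) {
            sim <- simulateCounterSet(config$simulate)
            truth <- sim$truth
            write.table(sim$truth$genes, file.path(outdir, "truth_genes.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            write.table(sim$truth$samples,
                        file.path(outdir, "truth_samples.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            sim$object
        } else if (!is.null(config$rccDir)) {
            readRccSet(config$rccDir, config$sampleSheet)
        } else {
            sheet <- config$sampleSheet
            if (is.character(sheet)) sheet <- read.delim(sheet)
            readCountsTsv(config$countsTsv, groups = sheet)
        }
    })
    writeCountsTsv(obj, file.path(outdir, "raw_counts.tsv"))

    bg <- stage("qc", estimateBackground(obj))
    hk <- stage("qc", {
        a <- screenHousekeeping(obj, bg, k = config$hkScreenK)
        a <- assessHousekeeping(obj, a)
        if (config$hkSelection == "correlation") {
            selectHkPanel(obj, a, minR = config$hkMinR,
                          panelSize = config$hkPanelSize)
        } else {
            rk <- genormRank(obj, passingHk(a))
            a@panel <- tail(rk$gene, config$hkPanelSize)
            a
        }
    })
    writeQcReport(bg, hk, outdir)
    logln("[qc] hk panel: ", paste(hkPanel(hk), collapse = ", "))

    obj <- stage("normalize", normalizeCounts(obj, hkPanel(hk)))
    writeNormalized(obj, outdir)

    det <- stage("detect",
                 scoreDetection(obj, bg, cutoff = config$snrCutoff,
                                minFraction = config$snrMinFraction,
                                scope = config$snrScope))
    writeDetection(det, file.path(outdir, "detection.tsv"))

    de <- stage("de", {
        d <- runDE(obj, detectedGenes(det), variant = config$tVariant,
                   fcMode = config$fcMode)
        callDegs(d, fcCutoff = config$fcCutoff, alpha = config$alpha,
                 correction = config$correction)
    })
    writeDeTables(de, outdir)

    collection <- stage("enrich", {
        files <- config$gmtFiles
        if (is.null(files))
            files <- system.file("extdata", "toy_immune.gmt",
                                 package = "nCounterFFPE")
        do.call(c, lapply(files, readGmt))
    })
    universe <- detectedGenes(det)
    up <- de$gene[de$call == "up"]; down <- de$gene[de$call == "down"]
    enrUp <- stage("enrich", suppressWarnings(ora(up, collection, universe)))
    enrDown <- stage("enrich", suppressWarnings(ora(down, collection, universe)))
    write.table(enrUp, file.path(outdir, "enrichment_up.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(enrDown, file.path(outdir, "enrichment_down.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    net <- stage("enrich", sharedTermNetwork(
        head(de$gene[order(de$p)][de$gene[order(de$p)] %in% c(up, down)], 20),
        collection))
    write.table(net, file.path(outdir, "shared_term_network.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    cl <- stage("report", {
        degs <- de$gene[de$call != "ns"]
        rowsUse <- if (length(degs) >= 2) degs else detectedGenes(det)
        clusterExpression(assay(obj, "log2")[rowsUse, , drop = FALSE],
                          linkage = config$linkage)
    })
    writeClusterReport(cl, outdir)

    counts <- c(n_probes = nrow(obj), n_samples = ncol(obj),
                n_hk = length(housekeepingNames(obj)),
                n_hk_passing = length(passingHk(hk)),
                n_detected = length(detectedGenes(det)),
                n_up = sum(de$call == "up"), n_down = sum(de$call == "down"))
    manifest <- list(package = "nCounterFFPE",
                     version = as.character(utils::packageVersion("nCounterFFPE")),
                     seed = config$seed,
                     hk_panel = hkPanel(hk),
                     config = config[!vapply(config, is.null, TRUE)],
                     counts = as.list(counts))
    manifest$config$simulate <- unclass(manifest$config$simulate)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    logln("[done] ", paste(names(counts), counts, sep = "=", collapse = " "))
    invisible(list(counts = counts, outdir = outdir, object = obj,
                   truth = truth, background = bg, hk = hk, detection = det,
                   de = de, enrichmentUp = enrUp, enrichmentDown = enrDown,
                   network = net, cluster = cl))
}
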