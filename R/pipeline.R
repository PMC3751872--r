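#' Default pipeline configuration
#'
#' Returns the full pipeline parameter list with every stage default;
#' fields supplied in `override` (possibly nested) replace the defaults.
#' The structure matches the YAML accepted by [runPipeline()].
#'
#' @param override named list of overrides.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(override = list()) {
    cfg <- list(
        seed = 1L,
        outdir = "evoshock-out",
        simulate = list(nGenes = 300L, deFraction = 0.1, deEffect = 2.0,
                        noiseSd = 0.25,
                        memorySpec = "default",
                        operons = TRUE, pools = TRUE),
        de = list(ratioCutoff = 1.0, zCutoff = 2.0),
        states = list(foldFilter = 2.0, nBoot = 200L),
        network = list(threshold = 0.98, rmt = FALSE, minModuleSize = 5L,
                       topHubs = 20L),
        operons = list(fold = 2.0, minDepth = 5, minPairs = 1L),
        mutations = list(generations = 440L, beneficialThreshold = 0.80))
    modifyNested <- function(base, upd) {
        for (nm in names(upd)) {
            base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
                modifyNested(base[[nm]], upd[[nm]]) else upd[[nm]]
        }
        base
    }
    modifyNested(cfg, override)
}

pipelineStage <- function(name, expr, log) {
    log(paste0("stage ", name, ": start"))
    out <- tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
    log(paste0("stage ", name, ": done"))
    out
}

#' Run the full microevolution analysis pipeline
#'
#' Executes simulate (all inputs generated with planted ground truth)
#' then differential expression, state-space analysis, co-expression
#' networks, operon dynamics and mutation analysis, writing per-stage
#' output files, a combined JSON report and a log (parameters, seed,
#' package version) under `outdir`.  Any stage failure aborts with the
#' stage name and cause.  Reruns with the same configuration and seed
#' produce identical outputs.
#'
#' @param config nested configuration list ([pipelineConfig()]) or the
#'   path to a YAML file with the same structure.
#' @return invisibly, the report list (also written as `report.json`).
#' @export
runPipeline <- function(config = pipelineConfig()) {
    if (is.character(config))
        config <- pipelineConfig(yaml::read_yaml(config))
    else
        config <- pipelineConfig(config)
    outdir <- config$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(outdir, "pipeline.log")
    logCon <- file(logPath, open = "wt")
    on.exit(close(logCon), add = TRUE)
    log <- function(msg) {
        line <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", msg)
        writeLines(line, logCon)
        message(line)
    }
    log(paste0("EvoShock ",
               as.character(utils::packageVersion("EvoShock")),
               ", seed ", config$seed))
    log(paste0("parameters: ",
               gsub("\n", " ", yaml::as.yaml(config))))
    report <- list(seed = config$seed,
                   version = as.character(
                       utils::packageVersion("EvoShock")))
    seed <- config$seed

    ## ---- simulate ----------------------------------------------------
    simOut <- pipelineStage("simulate", {
        sc <- config$simulate
        memorySpec <- list()
        if (identical(sc$memorySpec, "default"))
            memorySpec <- list(list(
                pair = list(c("XII-0%", "X-0%"), c("X-0.15%-4h", "X-0%")),
                nGenes = 40L, sd = 1.5))
        cfg <- simConfig(nGenes = sc$nGenes, deFraction = sc$deFraction,
                         deEffect = sc$deEffect, noiseSd = sc$noiseSd,
                         memorySpec = memorySpec, seed = seed)
        sim <- simulateExpression(cfg)
        writeExpression(sim$expression,
                        file.path(outdir, "expression.tsv"),
                        file.path(outdir, "samples.tsv"))
        genomeSim <- simulateGenome(nGenes = 12L, seed = seed)
        writeGenome(genomeSim$genome, file.path(outdir, "genome.fasta"))
        writeAnnotation(genomeSim$genes, file.path(outdir, "genes.gff3"))
        operonReads <- NULL
        if (isTRUE(sc$operons)) {
            ## condition c1 carries a planted split in poly1; c2 does not
            specC1 <- list(list(id = "poly1",
                                genes = genomeSim$genes$gene_id[1:4],
                                splits = 2L, depthMult = c(3, 3, 1, 1)),
                           list(id = "poly2",
                                genes = genomeSim$genes$gene_id[5:8],
                                splits = integer(0),
                                depthMult = rep(1, 4)))
            specC2 <- lapply(specC1, function(op) {
                op$splits <- integer(0)
                op$depthMult <- rep(1, length(op$genes))
                op
            })
            readsC1 <- simulateOperonReads(
                genomeSim$genes, specC1, depth = 100, seed = seed,
                conditions = "c1")
            readsC2 <- simulateOperonReads(
                genomeSim$genes, specC2, depth = 100, seed = seed + 1L,
                conditions = "c2")
            operonReads <- list(
                coverage = c(readsC1$coverage, readsC2$coverage),
                links = rbind(readsC1$links, readsC2$links))
            spec <- specC1
            writeLinks(operonReads$links, file.path(outdir, "links.tsv"))
            for (cond in names(operonReads$coverage))
                for (r in seq_along(operonReads$coverage[[cond]]))
                    writeCoverage(operonReads$coverage[[cond]][[r]],
                                  file.path(outdir, paste0(
                                      "coverage-", cond, "-r", r,
                                      ".bedGraph")))
            operonReads$spec <- spec
        }
        pool <- NULL
        mutTruth <- NULL
        if (isTRUE(sc$pools)) {
            mutTruth <- plantMutations(
                genomeSim,
                c("missense", "missense", "nonsense", "synonymous",
                  "intergenic", "frameshift"), seed = seed)
            pool <- simulatePoolReads(
                data.frame(chrom = mutTruth$chrom, pos = mutTruth$pos,
                           ref = mutTruth$ref, alt = mutTruth$alt,
                           freq = rep(c(0.9, 0.5), length.out =
                                          nrow(mutTruth))),
                depth = 140, seed = seed)
            writePoolCounts(pool, file.path(outdir, "pool.tsv"))
        }
        list(sim = sim, genomeSim = genomeSim, operonReads = operonReads,
             pool = pool, mutTruth = mutTruth)
    }, log)

    expr <- simOut$sim$expression

    ## ---- differential expression -------------------------------------
    deOut <- pipelineStage("de", {
        res <- list()
        for (p in defaultContrasts()) {
            ratios <- contrastLogRatios(expr, p[1], p[2])
            de <- callDE(ratios, config$de$ratioCutoff, config$de$zCutoff)
            lab <- relLabel(p[1], p[2])
            utils::write.table(
                data.frame(gene = rownames(de), as.data.frame(de)),
                file.path(outdir, paste0(
                    "de-", gsub("[^A-Za-z0-9.-]", "_", lab), ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
            res[[lab]] <- de
        }
        res
    }, log)
    report$de <- lapply(deOut, function(d) sum(d$significant))

    ## ---- state space --------------------------------------------------
    statesOut <- pipelineStage("states", {
        prof <- absoluteStates(expr)
        rel <- relativeStates(expr, foldFilter = config$states$foldFilter)
        dmAbs <- stateDistances(prof, "absolute")
        dmRel <- stateDistances(rel, "relative")
        writeDistances(dmAbs, file.path(outdir, "distances-absolute.tsv"))
        writeDistances(dmRel, file.path(outdir, "distances-relative.tsv"))
        bt <- bootstrapTree(prof, nBoot = config$states$nBoot, seed = seed)
        writeSupportTree(bt, file.path(outdir, "states-tree.nwk"))
        metrics <- microevolutionMetrics(
            dmAbs, dmRel,
            groups = list(c("X-0%", "X-0.15%-0.5h", "X-0.15%-1h",
                            "X-0.15%-2h", "X-0.15%-4h"),
                          c("XI-0%", "XI-2%", "XII-0%", "XII-6%")),
            trajectory = c("X-0.15%-0.5h", "X-0.15%-1h", "X-0.15%-2h",
                           "X-0.15%-4h"),
            discreteState = "XII-6%")
        metrics
    }, log)
    report$states <- list(
        convergencePair = statesOut$convergence$pair,
        convergenceDistance = statesOut$convergence$distance,
        nRelativePairs = nrow(statesOut$memory))

    ## ---- co-expression networks ---------------------------------------
    netOut <- pipelineStage("network", {
        shockStates <- grep("^X-0.15%", unique(stateLabels(expr)),
                            value = TRUE)
        controlStates <- setdiff(unique(stateLabels(expr)),
                                 c(shockStates))
        cmShock <- geneCorrelations(expr, shockStates)
        cmCtrl <- geneCorrelations(expr, controlStates)
        thr <- config$network$threshold
        if (isTRUE(config$network$rmt))
            thr <- rmtThreshold(cmShock)$threshold
        netA <- buildNetwork(cmShock, thr)
        netB <- buildNetwork(cmCtrl, thr)
        writeNetwork(netA, file.path(outdir, "network-shock.tsv"),
                     file.path(outdir, "network-shock.graphml"))
        writeNetwork(netB, file.path(outdir, "network-control.tsv"),
                     file.path(outdir, "network-control.graphml"))
        cmp <- NULL
        if (length(networkNodes(netA)) && length(networkNodes(netB)))
            cmp <- compareNetworks(netA, netB, k = config$network$topHubs)
        list(netA = netA, netB = netB, cmp = cmp)
    }, log)
    report$network <- list(
        shockNodes = length(networkNodes(netOut$netA)),
        controlNodes = length(networkNodes(netOut$netB)),
        shrinkagePercent = if (!is.null(netOut$cmp))
            netOut$cmp$shrinkagePercent else NA)

    ## ---- operon dynamics ----------------------------------------------
    operonOut <- pipelineStage("operons", {
        if (is.null(simOut$operonReads)) return(NULL)
        or <- simOut$operonReads
        models <- list()
        for (cond in names(or$coverage)) {
            covTab <- do.call(rbind, lapply(
                seq_along(or$coverage[[cond]]), function(r) {
                    sc <- summarizeCoverage(or$coverage[[cond]][[r]],
                                            simOut$genomeSim$genes,
                                            config$operons$minDepth)
                    sc$replicate <- r
                    sc
                }))
            models[[cond]] <- lapply(or$spec, function(op)
                callSuboperons(list(id = op$id, genes = op$genes),
                               covTab,
                               or$links[or$links$condition == cond, ],
                               fold = config$operons$fold,
                               minDepth = config$operons$minDepth,
                               minPairs = config$operons$minPairs,
                               condition = cond))
        }
        calls <- compareOperons(models[[1]], models[[2]])
        utils::write.table(calls, file.path(outdir, "operon-calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        list(models = models, calls = calls)
    }, log)
    if (!is.null(operonOut))
        report$operons <- list(
            models = length(operonOut$models[[1]]),
            dynamicCalls = nrow(operonOut$calls))

    ## ---- mutation analysis --------------------------------------------
    mutOut <- pipelineStage("mutations", {
        if (is.null(simOut$mutTruth)) return(NULL)
        truth <- simOut$mutTruth
        callSet <- truth[, c("chrom", "pos", "ref", "alt")]
        cons <- consensusCalls(list(maq = callSet, samtools = callSet,
                                    gatk = callSet))
        ann <- annotateEffects(cons$consensus, simOut$genomeSim$genes,
                               simOut$genomeSim$genome)
        pool <- pooledFrequency(simOut$pool)
        ann <- attachPoolFrequencies(ann, pool)
        ann <- beneficialCalls(ann, config$mutations$beneficialThreshold)
        writeVcfCalls(ann, file.path(outdir, "mutations.vcf"))
        prof <- mutationProfile(ann)
        muG <- mutationRate(nrow(ann), config$mutations$generations)
        list(calls = ann, profile = prof, muG = muG)
    }, log)
    if (!is.null(mutOut))
        report$mutations <- list(
            total = mutOut$profile$total,
            nonCodingCodingPercent = mutOut$profile$nonCodingCodingPercent,
            muG = mutOut$muG,
            beneficial = nrow(mutOut$profile$beneficial))

    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log("pipeline complete")
    invisible(report)
}
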