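#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run: simulate (or
#' load) proteomes, cluster, refine, build the supermatrix, reconstruct
#' gains/losses, and extract clade signatures.
#'
#' @param outputDir directory for all stage outputs.
#' @param seed integer seed controlling the simulator (and recorded in
#'   every output header).
#' @param simulation a \code{\link{simulationConfig}}; used when
#'   \code{inputFasta} is NULL.  Its seed is overridden by \code{seed}.
#' @param inputFasta optional directory of per-genome FASTA proteomes;
#'   switches the pipeline to real input.
#' @param speciesTreePath optional Newick species tree (required with
#'   \code{inputFasta}); midpoint-rooted with a warning if unrooted.
#' @param minIdentity,minCoverage similarity-search thresholds.
#' @param maxIterations,minSpan,minScorePerColumn refinement parameters.
#' @param maxExtraParalogs,perGenome marker selection parameters.
#' @param maxGapFraction,minHomogeneity column filter parameters.
#' @param ascertainment gain/loss ascertainment correction flag.
#' @param eventThreshold posterior-change magnitude for event calls.
#' @param clade genome ids of the focal clade for signature queries;
#'   NULL picks the smaller clade under the species-tree root.
#' @param commonFraction "common outside the clade" threshold.
#' @param aligner,treeBuilder optional external-tool hooks (see
#'   \code{\link{alignCluster}}, \code{\link{buildGeneTree}}).
#' @return A list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(outputDir, seed = 1L,
                           simulation = simulationConfig(),
                           inputFasta = NULL, speciesTreePath = NULL,
                           minIdentity = 0.5, minCoverage = 0.5,
                           maxIterations = 5L, minSpan = 0.8,
                           minScorePerColumn = 0.5,
                           maxExtraParalogs = 4L, perGenome = FALSE,
                           maxGapFraction = 0.667, minHomogeneity = 0.05,
                           ascertainment = TRUE, eventThreshold = 0.5,
                           clade = NULL, commonFraction = 0.667,
                           aligner = NULL, treeBuilder = NULL) {
    simulation$seed <- as.integer(seed)
    structure(list(
        outputDir = outputDir, seed = as.integer(seed),
        simulation = simulation, inputFasta = inputFasta,
        speciesTreePath = speciesTreePath, minIdentity = minIdentity,
        minCoverage = minCoverage,
        maxIterations = as.integer(maxIterations), minSpan = minSpan,
        minScorePerColumn = minScorePerColumn,
        maxExtraParalogs = as.integer(maxExtraParalogs),
        perGenome = perGenome, maxGapFraction = maxGapFraction,
        minHomogeneity = minHomogeneity, ascertainment = ascertainment,
        eventThreshold = eventThreshold, clade = clade,
        commonFraction = commonFraction, aligner = aligner,
        treeBuilder = treeBuilder), class = "PipelineConfig")
}

## stable hash of the scientific parameters of a config
.configHash <- function(config) {
    keep <- config[setdiff(names(config),
                           c("outputDir", "aligner", "treeBuilder"))]
    keep$simulation <- unclass(keep$simulation)
    txt <- jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA,
                            null = "null")
    f <- tempfile()
    writeLines(as.character(txt), f)
    h <- unname(tools::md5sum(f))
    unlink(f)
    h
}

#' Run the full pipeline
#'
#' Executes the stages in order -- simulate (or load), cluster, refine,
#' supermatrix, gain/loss, signatures -- writing each stage's standard
#' outputs under \code{outputDir} and returning a run report.  Rerunning
#' with an identical configuration reproduces identical data outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return Invisibly, the report (also written as \code{report.json}).
#' @export
runPipeline <- function(config) {
    t0 <- Sys.time()
    out <- config$outputDir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    hash <- .configHash(config)
    hdr <- .headerLines(config$seed, hash)
    report <- list(tool = "phyloCOG",
                   version = tryCatch(
                       as.character(utils::packageVersion("phyloCOG")),
                       error = function(e) "0.0.0"),
                   seed = config$seed, config_hash = hash)

    ## ---- stage 1: inputs --------------------------------------------
    truth <- NULL
    if (is.null(config$inputFasta)) {
        sim <- simulateGenomeSet(config$simulation)
        gs <- sim$genomes
        stree <- sim$tree
        truth <- sim$truth
        writeGenomeSet(gs, file.path(out, "genomes"))
        writeSpeciesTree(stree, file.path(out, "species_tree.nwk"))
        ev <- trueEvents(truth)
        .writeTSV(data.frame(edge_child_node = ev$child,
                             family = ev$family, event_type = ev$type),
                  file.path(out, "truth_events.tsv"), hdr)
        writePhyleticMatrix(trueMatrix(truth),
                            file.path(out, "truth_matrix.tsv"), hdr)
        report$n_dropped_families <- truth@nDropped
    } else {
        gs <- readGenomeSet(config$inputFasta)
        if (is.null(config$speciesTreePath))
            stop("stage input: a species tree is required with inputFasta")
        stree <- readSpeciesTree(config$speciesTreePath)
        if (!ape::is.rooted(stree)) {
            warning("species tree is unrooted; applying midpoint rooting")
            stree <- midpointRoot(stree)
        }
        report$input_files <- list.files(config$inputFasta,
                                         full.names = TRUE)
        report$input_md5 <- unname(tools::md5sum(
            sort(report$input_files)))
    }
    report$n_proteins <- length(gs)
    report$n_genomes <- length(genomeNames(gs))

    ## ---- stage 2: clustering ----------------------------------------
    hits <- allVsAllSimilarity(gs, minIdentity = config$minIdentity,
                               minCoverage = config$minCoverage)
    cs <- greedyCluster(hits, gs)
    cs <- attachSequences(cs, gs)
    cs <- refineClusters(cs, maxIterations = config$maxIterations,
                         minSpan = config$minSpan,
                         minScorePerColumn = config$minScorePerColumn,
                         aligner = config$aligner,
                         treeBuilder = config$treeBuilder)
    writeClusterTable(cs, file.path(out, "clusters.tsv"), hdr)
    rl <- cs@metadata$refinementLog
    writeLines(vapply(seq_len(nrow(rl)), function(i)
        as.character(jsonlite::toJSON(as.list(rl[i, ]),
                                      auto_unbox = TRUE)), ""),
        file.path(out, "refinement_log.jsonl"))
    mat <- phyleticMatrix(cs, genomes = sort(genomeNames(gs)))
    writePhyleticMatrix(mat, file.path(out, "phyletic_matrix.tsv"), hdr)
    report$n_clusters <- length(cs)
    report$n_singletons <- length(singletons(cs))
    report$refinement_log <- rl

    ## ---- stage 3: supermatrix ---------------------------------------
    smr <- tryCatch(
        buildSupermatrix(cs, genomes = sort(genomeNames(gs)),
                         maxExtraParalogs = config$maxExtraParalogs,
                         perGenome = config$perGenome,
                         maxGapFraction = config$maxGapFraction,
                         minHomogeneity = config$minHomogeneity),
        error = function(e) e)
    if (inherits(smr, "error"))
        stop("stage supermatrix: ", conditionMessage(smr))
    writeSupermatrix(smr$supermatrix,
                     file.path(out, "supermatrix.fasta"),
                     file.path(out, "supermatrix.phy"))
    writePartitions(smr$supermatrix, file.path(out, "partitions.txt"))
    .writeTSV(smr$filterStats, file.path(out, "markers.tsv"), hdr)
    report$n_markers <- length(smr$markers)
    w <- Biostrings::width(superAlignment(smr$supermatrix))
    report$supermatrix_sites <- if (length(w)) w[1L] else 0L
    report$columns_kept <- sum(smr$filterStats$kept)
    report$columns_removed <- sum(smr$filterStats$removed)

    ## ---- stage 4: gain/loss -----------------------------------------
    model <- fitRates(mat, stree, ascertainment = config$ascertainment)
    post <- marginalPosteriors(stree, mat, model)
    events <- callEvents(post, stree, threshold = config$eventThreshold)
    writePosteriors(post, file.path(out, "posteriors.tsv"), hdr)
    writeEventCalls(events, file.path(out, "events.tsv"), hdr)
    writeAncestralContent(post, file.path(out, "ancestral_content.tsv"),
                          hdr)
    writeModelJSON(model, file.path(out, "model.json"))
    report$gain_rate <- model@gainRate
    report$loss_rate <- model@lossRate
    report$log_likelihood <- model@logLik
    report$n_gain_events <- sum(events$type == "gain")
    report$n_loss_events <- sum(events$type == "loss")

    ## ---- stage 5: signatures ----------------------------------------
    clade <- config$clade
    if (is.null(clade)) {
        root <- ape::Ntip(stree) + 1L
        kids <- stree$edge[stree$edge[, 1L] == root, 2L]
        sets <- lapply(kids, function(v)
            stree$tip.label[.cladeTips(stree, v)])
        clade <- sets[[which.min(lengths(sets))]]
    }
    anc <- .cladeAncestorNode(stree, clade)
    sig <- cladeSignatures(mat, clade,
                           commonFraction = config$commonFraction,
                           posteriors = post, ancestorNode = anc)
    .writeTSV(data.frame(family = sig$core),
              file.path(out, "clade_core.tsv"), hdr)
    .writeTSV(data.frame(family = sig$gains),
              file.path(out, "clade_gains.tsv"), hdr)
    .writeTSV(data.frame(family = sig$absent),
              file.path(out, "clade_absent.tsv"), hdr)
    .writeTSV(data.frame(
        statistic = c("clade_size", "core", "gains", "absent_common",
                      "ancestral_content"),
        value = c(length(clade), sig$n_core, sig$n_gains, sig$n_absent,
                  round(sig$ancestral_content, 4L))),
        file.path(out, "signature_summary.tsv"), hdr)
    report$clade <- clade
    report$clade_ancestor <- anc
    report$n_core <- sig$n_core
    report$n_clade_gains <- sig$n_gains
    report$n_clade_absent <- sig$n_absent
    report$ancestral_content <- sig$ancestral_content

    report$wall_time_sec <- as.numeric(Sys.time() - t0, units = "secs")
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(report)
}

## node label of the MRCA of a set of tips
.cladeAncestorNode <- function(tree, clade) {
    tips <- match(clade, tree$tip.label)
    if (anyNA(tips)) stop("clade genomes not in tree")
    node <- if (length(tips) == 1L) tips[1L] else
        ape::getMRCA(tree, tips)
    nodeNames(tree)[node]
}
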