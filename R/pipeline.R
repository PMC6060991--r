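# End-to-end orchestration: counts -> DEG x 3 -> set logic -> enrichment ->
# miRNA integration, file-in / file-out, with a machine-readable manifest.

defaultPipelineConfig <- function() {
    list(
        comparisons = list(V1F2 = c("V1", "F2"),
                           V1V2 = c("V1", "V2"),
                           V2F2 = c("V2", "F2")),
        fdr_max = 0.001,
        abs_log2_min = 1,
        pseudocount = 1,
        set_expression = "(V1F2 & V2F2) - V1V2",
        alpha = 0.05,
        correction = "BH",
        seed = 1L)
}

#' Read a pipeline configuration
#'
#' @param path YAML file with input paths, library sizes, thresholds and
#'   output directory (see [runPipeline()] for the recognized fields).
#' @return Config list with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    out <- utils::modifyList(defaultPipelineConfig(), cfg)
    out
}

pipelineLog <- function(stage, ...) {
    message("[", stage, "] ", ...)
}

checkConfig <- function(config) {
    need <- c("counts", "gene_lengths", "mirnas", "targets", "annotations",
              "library_sizes", "outdir")
    miss <- setdiff(need, names(config))
    if (length(miss))
        stopValidation("pipeline config is missing field(s): ",
                       paste(miss, collapse = ", "))
    for (f in c("counts", "gene_lengths", "mirnas", "targets",
                "annotations", "terms")) {
        if (!is.null(config[[f]]) && !file.exists(config[[f]]))
            stopValidation("config field '", f, "': file not found: ",
                           config[[f]])
    }
    ls <- unlist(config$library_sizes)
    labs <- unique(unlist(config$comparisons))
    if (!all(labs %in% names(ls)))
        stopValidation("comparisons reference library labels missing from ",
                       "library_sizes: ",
                       paste(setdiff(labs, names(ls)), collapse = ", "))
    invisible(config)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order: RPKM normalization, the Audic-Claverie DEG screen
#' for the three pairwise comparisons, set logic yielding Venn-region
#' counts and the flowering-exclusive gene set, hypergeometric term
#' enrichment of that set (when a term map is configured), and the
#' miRNA-mRNA antagonistic-pair integration on the V1-vs-F2 comparison.
#' Every stage reads and writes plain files under `config$outdir`, so
#' stages are independently re-runnable; a failure leaves the outputs of
#' completed stages intact and reports the failing stage.
#'
#' Config fields: `counts`, `gene_lengths`, `mirnas`, `targets`,
#' `annotations` (input TSV paths), optional `terms`, `library_sizes`
#' (named list of total mapped tags), `comparisons` (named list of
#' reference/test label pairs; defaults to the three study comparisons),
#' `fdr_max` (0.001), `abs_log2_min` (1), `pseudocount` (1),
#' `set_expression` (`"(V1F2 & V2F2) - V1V2"`), `alpha` (0.05),
#' `correction` (`"BH"`), `outdir`, `seed`.
#'
#' @param config Config list or path to a YAML file ([readPipelineConfig()]).
#' @param force Overwrite outputs of a previous run in the same `outdir`?
#'   Without `force`, an existing manifest causes a refusal.
#' @return The run manifest (invisibly): config echo, per-stage record
#'   counts, package version, wall time, seed. Also written as
#'   `manifest.json` in `outdir`.
#' @export
runPipeline <- function(config, force = FALSE) {
    if (is.character(config) && length(config) == 1L)
        config <- readPipelineConfig(config)
    config <- utils::modifyList(defaultPipelineConfig(), config)
    checkConfig(config)
    outdir <- config$outdir
    manifestPath <- file.path(outdir, "manifest.json")
    if (file.exists(manifestPath) && !force)
        stopValidation("outputs already exist in ", outdir,
                       "; re-run with force = TRUE to overwrite")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    t0 <- Sys.time()
    nrec <- list()
    runStage <- function(stage, fn) {
        pipelineLog(stage, "starting")
        tryCatch(fn(), error = function(e) {
            stop("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e), call. = FALSE)
        })
    }

    # expression stage
    libSizes <- unlist(config$library_sizes)
    dge <- runStage("expression", function() {
        tab <- readTsv(config$counts)
        m <- as.matrix(tab[, -1, drop = FALSE])
        rownames(m) <- tab[[1]]
        DGECountSet(m, libSizes[colnames(m)])
    })
    lengths <- readTsv(config$gene_lengths)
    rpkmTab <- runStage("expression", function() {
        r <- rpkmMatrix(dge, lengths)
        out <- data.frame(gene_id = rownames(r), r, check.names = FALSE)
        writeTsv(out, file.path(outdir, "rpkm.tsv"))
        out
    })
    nrec$rpkm_genes <- nrow(rpkmTab)

    # deg stage, one screen per comparison
    degs <- runStage("deg", function() {
        lapply(config$comparisons, function(cmp) {
            d <- screenDEGs(dge, cmp,
                            fdrMax = config$fdr_max,
                            absLog2Min = config$abs_log2_min,
                            pseudocount = config$pseudocount,
                            geneLengths = stats::setNames(lengths$length,
                                                          lengths$gene_id))
            d
        })
    })
    for (lab in names(degs)) {
        writeTsv(degs[[lab]], file.path(outdir, paste0("deg_", lab, ".tsv")))
        s <- degSummary(degs[[lab]])
        nrec[[paste0("deg_", lab, "_tested")]] <- nrow(degs[[lab]])
        nrec[[paste0("deg_", lab, "_up")]] <- unname(s["n_up"])
        nrec[[paste0("deg_", lab, "_down")]] <- unname(s["n_down"])
        pipelineLog("deg", lab, ": ", s["n_up"], " up / ",
                    s["n_down"], " down of ", nrow(degs[[lab]]), " tested")
    }

    # set-logic stage
    sets <- comparisonSets(degs$V1F2, degs$V1V2, degs$V2F2)
    flowering <- runStage("sets", function() {
        venn <- vennCounts(sets)
        jsonlite::write_json(as.list(venn), file.path(outdir, "venn.json"),
                             auto_unbox = TRUE)
        fl <- floweringExclusiveGenes(sets, config$set_expression)
        writeLines(fl, file.path(outdir, "flowering_genes.txt"))
        fl
    })
    nrec$flowering_genes <- length(flowering)
    pipelineLog("sets", length(flowering), " flowering-exclusive genes")

    # enrichment stage (optional)
    if (!is.null(config$terms)) {
        runStage("enrich", function() {
            terms <- readTsv(config$terms)
            population <- rownames(counts(dge))[rowSums(counts(dge)) > 0]
            study <- intersect(flowering, population)
            if (!length(study)) {
                pipelineLog("enrich", "empty study set; stage skipped")
                nrec$enriched_terms <<- 0L
                return(invisible(NULL))
            }
            res <- enrich(study, population, terms,
                          alpha = config$alpha,
                          correction = config$correction)
            writeTsv(res, file.path(outdir, "enrichment.tsv"))
            writeTsv(categoryBreakdown(study, terms),
                     file.path(outdir, "go_breakdown.tsv"))
            nrec$enrichment_terms_tested <<- nrow(res)
            nrec$enriched_terms <<- sum(res$enriched)
            pipelineLog("enrich", sum(res$enriched), " of ", nrow(res),
                        " terms enriched at alpha = ", config$alpha)
        })
    }

    # integration stage (V1-vs-F2 comparison, as in the study design)
    runStage("pairs", function() {
        mirnas <- readTsv(config$mirnas)
        targets <- readTsv(config$targets)
        annotations <- readTsv(config$annotations)
        pairs <- antagonisticPairs(mirnas, degs$V1F2, targets)
        writeTsv(pairs, file.path(outdir, "pairs.tsv"))
        grouped <- groupByMirna(pairs)
        flat <- grouped
        flat$targets <- vapply(grouped$targets, paste, character(1),
                               collapse = ",")
        writeTsv(flat, file.path(outdir, "pairs_by_mirna.tsv"))
        fpairs <- filterFlowering(pairs, annotations)
        writeTsv(fpairs, file.path(outdir, "flowering_pairs.tsv"))
        s <- pairSummary(pairs)
        nrec$pair_records <<- nrow(pairs)
        nrec$pair_mirnas <<- nrow(grouped)
        nrec$pair_mirna_up <<- unname(s["n_mirna_up"])
        nrec$pair_mirna_down <<- unname(s["n_mirna_down"])
        nrec$flowering_pairs <<- nrow(fpairs)
        pipelineLog("pairs", nrow(pairs), " antagonistic pairs over ",
                    nrow(grouped), " miRNAs; ", nrow(fpairs),
                    " flowering-annotated")
    })

    manifest <- list(
        config = config[setdiff(names(config), "outdir_internal")],
        counts = nrec,
        version = as.character(utils::packageVersion("floweringDGE")),
        wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
        seed = config$seed)
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    pipelineLog("done", "manifest written to ", manifestPath)
    invisible(manifest)
}

#' Write a small simulated demo study to disk
#'
#' Simulates a compact three-library study with planted truth and writes
#' every pipeline input (counts, gene lengths, DE-miRNA table, target map,
#' annotations, a synthetic term map), the ground-truth JSON and a ready
#' `config.yaml`, so documentation examples and tests run in seconds.
#'
#' @param seed Integer seed for the simulation.
#' @param outdir Directory to create the demo in.
#' @param nGenes Number of simulated genes (default 2000).
#' @param librarySize Tags per library (default 1e6 each).
#' @return List with `config` (the pipeline config list), `configPath`,
#'   and `truth` (the [SimTruth-class]).
#' @export
makeDemo <- function(seed = 1L, outdir, nGenes = 2000,
                     librarySize = 1e6) {
    if (missing(outdir))
        stopValidation("'outdir' is required")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outdir))
        stop("cannot create demo directory ", outdir, call. = FALSE)
    cfg <- SimConfig(nGenes = nGenes,
                     librarySizes = c(V1 = librarySize, V2 = librarySize,
                                      F2 = librarySize),
                     seed = seed)
    sim <- simulateCountLibraries(cfg)
    mt <- simulateMirnaTables(cfg, sim$truth)
    cts <- counts(sim$counts)
    writeTsv(data.frame(gene_id = rownames(cts), cts, check.names = FALSE),
             file.path(outdir, "counts.tsv"))
    set.seed(cfg@seed + 2L)
    genes <- rownames(cts)
    writeTsv(data.frame(gene_id = genes,
                        length = sample(300:5000, length(genes),
                                        replace = TRUE)),
             file.path(outdir, "gene_lengths.tsv"))
    writeTsv(mt$mirnas, file.path(outdir, "mirnas.tsv"))
    writeTsv(mt$targets, file.path(outdir, "targets.tsv"))
    writeTsv(mt$annotations, file.path(outdir, "annotations.tsv"))
    nTerms <- 30L
    terms <- do.call(rbind, lapply(seq_len(nTerms), function(i) {
        ns <- termNamespaces[(i - 1L) %% length(termNamespaces) + 1L]
        data.frame(term_id = sprintf("TERM%03d", i),
                   gene_id = sample(genes, sample(10:50, 1)),
                   namespace = ns,
                   description = paste("synthetic term", i),
                   stringsAsFactors = FALSE)
    }))
    writeTsv(terms, file.path(outdir, "terms.tsv"))
    truth <- mt$truth
    jsonlite::write_json(
        list(de_status = as.data.frame(truth@deStatus),
             gene_id = rownames(truth@deStatus),
             mirna_direction = as.list(truth@mirnaDirection),
             true_pairs = truth@truePairs),
        file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
    config <- utils::modifyList(defaultPipelineConfig(), list(
        counts = file.path(outdir, "counts.tsv"),
        gene_lengths = file.path(outdir, "gene_lengths.tsv"),
        mirnas = file.path(outdir, "mirnas.tsv"),
        targets = file.path(outdir, "targets.tsv"),
        annotations = file.path(outdir, "annotations.tsv"),
        terms = file.path(outdir, "terms.tsv"),
        library_sizes = as.list(cfg@librarySizes),
        outdir = file.path(outdir, "results"),
        seed = as.integer(seed)))
    configPath <- file.path(outdir, "config.yaml")
    yaml::write_yaml(config, configPath)
    list(config = config, configPath = configPath, truth = mt$truth)
}
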