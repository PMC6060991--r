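# Synthetic three-library DGE study generator with planted ground truth.

simComparisons <- function() {
    # reference library, test library, per comparison label
    list(V1F2 = c("V1", "F2"), V1V2 = c("V1", "V2"), V2F2 = c("V2", "F2"))
}

#' Simulate three tag-count libraries with planted differential expression
#'
#' Draws a log-normal baseline expression profile over `nGenes` genes
#' (renormalized so gene-assigned tags form `geneTagFraction` of each
#' library), plants differential expression in disjoint gene subsets for
#' each of the three pairwise comparisons by multiplying the test library's
#' rate by a fold of |log2| drawn from `log2FoldRange` (sign at random),
#' and samples counts as Poisson(rate x library size) — the sampling model
#' of the Audic-Claverie test; the design has one library per condition, so
#' no biological-replicate dispersion exists to model. The returned truth
#' derives each gene's per-comparison status from the realized rate ratios,
#' because a fold planted in one library necessarily shows up in both
#' comparisons involving that library.
#'
#' @param config A [SimConfig-class]. All randomness derives from
#'   `config@seed`; the same config yields bit-identical output.
#' @return List with `counts` (a [DGECountSet-class] of the three libraries
#'   V1, V2, F2) and `truth` (a [SimTruth-class]).
#' @examples
#' sim <- simulateCountLibraries(SimConfig(nGenes = 200, seed = 7))
#' sim$counts
#' @export
simulateCountLibraries <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    genes <- sprintf("gene%05d", seq_len(config@nGenes))
    base <- 10^stats::rnorm(config@nGenes, config@baselineMeanLog10,
                            config@baselineSdLog10)
    base <- base / sum(base) * config@geneTagFraction
    names(base) <- genes
    rate <- cbind(V1 = base, V2 = base, F2 = base)
    cmp <- simComparisons()
    nDE <- vapply(config@fracDE, function(f) round(f * config@nGenes),
                  numeric(1))
    pool <- sample(genes)  # random order; disjoint slices per comparison
    offset <- 0
    for (lab in names(cmp)) {
        n <- min(nDE[[lab]], length(pool) - offset)
        if (n <= 0) next
        planted <- pool[seq_len(n) + offset]
        offset <- offset + n
        mag <- stats::runif(n, config@log2FoldRange[1],
                            config@log2FoldRange[2])
        sgn <- sample(c(-1, 1), n, replace = TRUE)
        testLib <- cmp[[lab]][2]
        rate[planted, testLib] <- rate[planted, testLib] * 2^(sgn * mag)
    }
    # planted up-folds inflate a library's total tag rate; rescale all
    # libraries by one common factor so gene tags stay within the library
    # total (ratios, and hence all planted truth, are unchanged)
    cap <- 0.95
    worst <- max(colSums(rate))
    if (worst > cap) {
        rate <- rate * (cap / worst)
        base <- base * (cap / worst)
    }
    lambda <- sweep(rate, 2, config@librarySizes, FUN = "*")
    cts <- matrix(stats::rpois(length(lambda), lambda),
                  nrow = config@nGenes,
                  dimnames = dimnames(lambda))
    trueLog2 <- vapply(cmp, function(p) {
        log2(rate[, p[2]] / rate[, p[1]])
    }, numeric(config@nGenes))
    deStatus <- matrix("null", config@nGenes, length(cmp),
                       dimnames = list(genes, names(cmp)))
    deStatus[trueLog2 > 1e-12] <- "up"
    deStatus[trueLog2 < -1e-12] <- "down"
    truth <- new("SimTruth",
                 deStatus = deStatus,
                 trueLog2 = trueLog2,
                 baselineRate = base,
                 mirnaDirection = character(),
                 truePairs = data.frame(mirna_id = character(),
                                        gene_id = character(),
                                        stringsAsFactors = FALSE))
    list(counts = DGECountSet(cts, config@librarySizes), truth = truth)
}

#' Simulate DE-miRNA, target-map and annotation tables
#'
#' Assigns each simulated miRNA a direction and draws its predicted targets
#' so that a fraction `fracOpposed` are sign-opposed in the V1-vs-F2
#' comparison (true antagonistic pairs, recorded in the returned truth) and
#' the rest are decoys whose V1-vs-F2 status is not opposed (same direction
#' or null). The annotation table flags `fracFloweringAnnotated` of all
#' genes as flowering-related.
#'
#' @param config The [SimConfig-class] used for the count simulation.
#' @param truth The [SimTruth-class] returned by
#'   [simulateCountLibraries()].
#' @return List with `mirnas` (`mirna_id`, `direction`, `novelty`),
#'   `targets` (`mirna_id`, `gene_id`), `annotations` (`gene_id`,
#'   `description`, `flowering`), and `truth` updated with
#'   `mirnaDirection` and `truePairs`.
#' @export
simulateMirnaTables <- function(config, truth) {
    stopifnot(is(config, "SimConfig"), is(truth, "SimTruth"))
    set.seed(config@seed + 1L)
    genes <- rownames(truth@deStatus)
    status <- truth@deStatus[, "V1F2"]
    mirnas <- sprintf("mir%03d", seq_len(config@nMirnas))
    novelty <- rep("known", config@nMirnas)
    if (config@nNovelMirnas > 0)
        novelty[sample(config@nMirnas, config@nNovelMirnas)] <- "novel"
    direction <- sample(c("up", "down"), config@nMirnas, replace = TRUE)
    names(direction) <- mirnas
    tgtRows <- list()
    trueRows <- list()
    for (m in mirnas) {
        k <- if (config@targetsPerMirna[1] == config@targetsPerMirna[2])
                 config@targetsPerMirna[1]
             else sample(seq(config@targetsPerMirna[1],
                             config@targetsPerMirna[2]), 1)
        opposedDir <- if (direction[[m]] == "up") "down" else "up"
        oppPool <- genes[status == opposedDir]
        decoyPool <- genes[status != opposedDir]
        nOpp <- min(round(config@fracOpposed * k), length(oppPool))
        nDecoy <- min(k - nOpp, length(decoyPool))
        opp <- if (nOpp) sample(oppPool, nOpp) else character()
        dec <- if (nDecoy) sample(decoyPool, nDecoy) else character()
        tgt <- sample(c(opp, dec))  # interleave presentation order
        if (length(tgt))
            tgtRows[[m]] <- data.frame(mirna_id = m, gene_id = tgt,
                                       stringsAsFactors = FALSE)
        if (length(opp))
            trueRows[[m]] <- data.frame(mirna_id = m, gene_id = opp,
                                        stringsAsFactors = FALSE)
    }
    targets <- if (length(tgtRows)) {
        t <- do.call(rbind, tgtRows)
        rownames(t) <- NULL
        t
    } else {
        data.frame(mirna_id = character(), gene_id = character(),
                   stringsAsFactors = FALSE)
    }
    truePairs <- if (length(trueRows)) {
        tp <- do.call(rbind, trueRows)
        rownames(tp) <- NULL
        tp
    } else {
        data.frame(mirna_id = character(), gene_id = character(),
                   stringsAsFactors = FALSE)
    }
    annotations <- data.frame(
        gene_id = genes,
        description = paste("simulated gene", seq_along(genes)),
        flowering = stats::runif(length(genes)) <
            config@fracFloweringAnnotated,
        stringsAsFactors = FALSE)
    truth@mirnaDirection <- direction
    truth@truePairs <- truePairs
    validObject(truth)
    list(mirnas = data.frame(mirna_id = mirnas, direction = direction,
                             novelty = novelty, stringsAsFactors = FALSE,
                             row.names = NULL),
         targets = targets,
         annotations = annotations,
         truth = truth)
}
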