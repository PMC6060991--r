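#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom BiocGenerics counts
NULL

#' Container for per-library digital gene expression tag counts
#'
#' A `DGECountSet` holds one non-negative integer tag count per gene per
#' sequencing library, together with the library sizes (total mapped tags)
#' that act as the denominators of RPKM normalization and as the N1/N2 of
#' the Audic-Claverie test. It extends
#' [SummarizedExperiment::SummarizedExperiment] with a `"counts"` assay and a
#' `librarySize` column in `colData`.
#'
#' Validity requires all counts to be non-negative and finite, every library
#' size to be a positive whole number, and the per-library count sum not to
#' exceed the library size (gene-mapped unambiguous tags are a subset of all
#' mapped tags).
#'
#' @seealso [DGECountSet()] for construction, [librarySizes()],
#'   [rpkmMatrix()], [screenDEGs()].
#' @export
setClass("DGECountSet", contains = "SummarizedExperiment")

setValidity("DGECountSet", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be finite and non-negative")
        if (any(abs(cts - round(cts)) > 1e-8))
            msg <- c(msg, "counts must be whole numbers (tag counts)")
    }
    if (!"librarySize" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData column 'librarySize' is required")
    else {
        ls <- SummarizedExperiment::colData(object)$librarySize
        if (any(!is.finite(ls)) || any(ls <= 0))
            msg <- c(msg, "library sizes must be positive")
        if ("counts" %in% SummarizedExperiment::assayNames(object)) {
            cs <- colSums(SummarizedExperiment::assay(object, "counts"))
            bad <- cs > ls
            if (any(bad))
                msg <- c(msg, paste0(
                    "per-library count sum exceeds library size for: ",
                    paste(colnames(object)[bad], collapse = ", ")))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a DGECountSet
#'
#' @param counts Numeric matrix of tag counts, genes in rows (rownames are
#'   gene identifiers), libraries in columns (colnames are library labels).
#' @param librarySizes Positive numeric vector of total mapped tags, one per
#'   library, in column order (names, if given, must match `colnames(counts)`).
#'
#' @return A [DGECountSet-class] object.
#' @examples
#' cts <- matrix(c(10L, 0L, 5L, 20L, 3L, 7L), nrow = 3,
#'               dimnames = list(paste0("g", 1:3), c("V1", "F2")))
#' dge <- DGECountSet(cts, librarySizes = c(V1 = 1e6, F2 = 1.2e6))
#' librarySizes(dge)
#' @export
DGECountSet <- function(counts, librarySizes) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("'counts' must have gene identifiers as rownames")
    if (is.null(colnames(counts)))
        stop("'counts' must have library labels as colnames")
    if (length(librarySizes) != ncol(counts))
        stop("'librarySizes' must have one entry per library (column)")
    if (!is.null(names(librarySizes))) {
        if (!setequal(names(librarySizes), colnames(counts)))
            stop("names of 'librarySizes' must match colnames(counts)")
        librarySizes <- librarySizes[colnames(counts)]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            librarySize = unname(as.numeric(librarySizes)),
            row.names = colnames(counts)))
    new("DGECountSet", se)
}

#' Configuration of the synthetic three-library study generator
#'
#' Parameters of the simulated digital-gene-expression study: three
#' sequencing libraries (labelled V1, V2 and F2 after the vegetative
#' single-flowering, vegetative double-flowering and flowering-stage
#' double-flowering samples of the emulated design), a log-normal baseline
#' expression profile, and planted differential expression of known
#' direction and fold for each pairwise comparison. Defaults reproduce the
#' scale of the emulated study: ~27,400 detected genes, three libraries of
#' 5.8-6.0 million mapped tags, ~10% of genes planted per comparison, and
#' 44 differentially expressed miRNAs (38 known, 6 novel).
#'
#' @slot nGenes Number of genes.
#' @slot librarySizes Named numeric of length 3 (tags) for V1, V2, F2.
#' @slot fracDE Named numeric in [0,1]: fraction of genes planted as DE in
#'   each comparison (`V1F2`, `V1V2`, `V2F2`). Planted sets are disjoint.
#' @slot log2FoldRange Numeric length 2, min >= 1: planted |log2 fold| drawn
#'   uniformly from this range (sign chosen at random).
#' @slot baselineMeanLog10,baselineSdLog10 Mean and SD of the log10 relative
#'   expression rate; rates are renormalized so gene-assigned tags make up
#'   `geneTagFraction` of each library.
#' @slot geneTagFraction Fraction of library tags attributed to genes.
#' @slot nMirnas Number of differentially expressed miRNAs.
#' @slot nNovelMirnas How many of `nMirnas` are flagged novel.
#' @slot targetsPerMirna Integer range (length 2): targets drawn per miRNA.
#' @slot fracOpposed Fraction of each miRNA's targets that are sign-opposed
#'   (true antagonistic pairs); the remainder are decoys.
#' @slot fracFloweringAnnotated Fraction of genes flagged flowering-related
#'   in the simulated annotation table.
#' @slot seed Integer seed; all generator randomness derives from it.
#' @seealso [SimConfig()], [simulateCountLibraries()], [simulateMirnaTables()]
#' @export
setClass("SimConfig", representation(
    nGenes = "integer",
    librarySizes = "numeric",
    fracDE = "numeric",
    log2FoldRange = "numeric",
    baselineMeanLog10 = "numeric",
    baselineSdLog10 = "numeric",
    geneTagFraction = "numeric",
    nMirnas = "integer",
    nNovelMirnas = "integer",
    targetsPerMirna = "integer",
    fracOpposed = "numeric",
    fracFloweringAnnotated = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (length(object@nGenes) != 1L || object@nGenes < 1L)
        msg <- c(msg, "nGenes must be a positive integer")
    if (length(object@librarySizes) != 3L || any(object@librarySizes <= 0))
        msg <- c(msg, "librarySizes must be three positive tag totals")
    if (!identical(names(object@librarySizes), c("V1", "V2", "F2")))
        msg <- c(msg, "librarySizes must be named V1, V2, F2")
    if (!identical(names(object@fracDE), c("V1F2", "V1V2", "V2F2")))
        msg <- c(msg, "fracDE must be named V1F2, V1V2, V2F2")
    if (any(object@fracDE < 0) || any(object@fracDE > 1))
        msg <- c(msg, "fracDE fractions must lie in [0,1]")
    if (sum(object@fracDE) > 1)
        msg <- c(msg, "fracDE fractions must sum to <= 1 (disjoint planting)")
    if (length(object@log2FoldRange) != 2L ||
        object@log2FoldRange[1] < 1 ||
        diff(object@log2FoldRange) < 0)
        msg <- c(msg, "log2FoldRange must be (min, max) with min >= 1")
    if (object@baselineSdLog10 < 0)
        msg <- c(msg, "baselineSdLog10 must be non-negative")
    if (object@geneTagFraction <= 0 || object@geneTagFraction > 1)
        msg <- c(msg, "geneTagFraction must lie in (0,1]")
    if (object@nMirnas < 0L || object@nNovelMirnas < 0L ||
        object@nNovelMirnas > object@nMirnas)
        msg <- c(msg, "need 0 <= nNovelMirnas <= nMirnas")
    if (length(object@targetsPerMirna) != 2L ||
        object@targetsPerMirna[1] < 1L ||
        diff(object@targetsPerMirna) < 0)
        msg <- c(msg, "targetsPerMirna must be an increasing positive range")
    if (object@targetsPerMirna[2] > object@nGenes)
        msg <- c(msg, "targetsPerMirna cannot exceed nGenes")
    if (object@fracOpposed < 0 || object@fracOpposed > 1)
        msg <- c(msg, "fracOpposed must lie in [0,1]")
    if (object@fracFloweringAnnotated < 0 || object@fracFloweringAnnotated > 1)
        msg <- c(msg, "fracFloweringAnnotated must lie in [0,1]")
    if (length(object@seed) != 1L || is.na(object@seed) ||
        abs(object@seed) > .Machine$integer.max - 10L)
        msg <- c(msg, "seed must be a single integer")
    if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nGenes,librarySizes,fracDE,log2FoldRange,baselineMeanLog10,baselineSdLog10,geneTagFraction,nMirnas,nNovelMirnas,targetsPerMirna,fracOpposed,fracFloweringAnnotated,seed
#'   See the slot documentation.
#' @return A validated `SimConfig`.
#' @examples
#' cfg <- SimConfig(nGenes = 500, librarySizes = c(V1 = 1e6, V2 = 1e6, F2 = 1e6))
#' @export
SimConfig <- function(nGenes = 27405L,
                      librarySizes = c(V1 = 5859055, V2 = 5973616,
                                       F2 = 5790541),
                      fracDE = c(V1F2 = 0.10, V1V2 = 0.10, V2F2 = 0.10),
                      log2FoldRange = c(1.5, 3),
                      baselineMeanLog10 = -4.5,
                      baselineSdLog10 = 0.8,
                      geneTagFraction = 0.75,
                      nMirnas = 44L,
                      nNovelMirnas = 6L,
                      targetsPerMirna = c(1L, 8L),
                      fracOpposed = 0.6,
                      fracFloweringAnnotated = 0.3,
                      seed = 1L) {
    if (is.null(names(librarySizes)))
        names(librarySizes) <- c("V1", "V2", "F2")
    if (is.null(names(fracDE)))
        names(fracDE) <- c("V1F2", "V1V2", "V2F2")
    new("SimConfig",
        nGenes = as.integer(nGenes),
        librarySizes = librarySizes[c("V1", "V2", "F2")],
        fracDE = fracDE[c("V1F2", "V1V2", "V2F2")],
        log2FoldRange = as.numeric(log2FoldRange),
        baselineMeanLog10 = as.numeric(baselineMeanLog10),
        baselineSdLog10 = as.numeric(baselineSdLog10),
        geneTagFraction = as.numeric(geneTagFraction),
        nMirnas = as.integer(nMirnas),
        nNovelMirnas = as.integer(nNovelMirnas),
        targetsPerMirna = as.integer(targetsPerMirna),
        fracOpposed = as.numeric(fracOpposed),
        fracFloweringAnnotated = as.numeric(fracFloweringAnnotated),
        seed = as.integer(seed))
}

#' Planted ground truth of a simulated study
#'
#' Records every effect planted by the generator so that recovery tests can
#' compare pipeline output against known truth.
#'
#' @slot deStatus Character matrix (gene x comparison) in
#'   \{"up","down","null"\}: the true differential-expression status of each
#'   gene in each pairwise comparison, derived from the realized per-library
#'   expression rates (a fold planted in one library perturbs both
#'   comparisons that involve it).
#' @slot trueLog2 Numeric matrix (gene x comparison): true log2 rate ratio
#'   (test over reference).
#' @slot baselineRate Named numeric: per-gene relative tag rate before fold
#'   perturbation; the expected count of a null gene in library l is
#'   `baselineRate * librarySizes[l]`.
#' @slot mirnaDirection Named character in \{"up","down"\} per simulated
#'   miRNA (empty until [simulateMirnaTables()] is run).
#' @slot truePairs data.frame with columns `mirna_id`, `gene_id`: the planted
#'   sign-opposed (antagonistic) miRNA-target pairs.
#' @export
setClass("SimTruth", representation(
    deStatus = "matrix",
    trueLog2 = "matrix",
    baselineRate = "numeric",
    mirnaDirection = "character",
    truePairs = "data.frame"))

setValidity("SimTruth", function(object) {
    msg <- character()
    if (!all(object@deStatus %in% c("up", "down", "null")))
        msg <- c(msg, "deStatus entries must be up/down/null")
    if (!identical(dim(object@deStatus), dim(object@trueLog2)))
        msg <- c(msg, "deStatus and trueLog2 must have identical shape")
    if (length(object@mirnaDirection) &&
        !all(object@mirnaDirection %in% c("up", "down")))
        msg <- c(msg, "mirnaDirection entries must be up/down")
    if (nrow(object@truePairs)) {
        need <- c("mirna_id", "gene_id")
        if (!all(need %in% colnames(object@truePairs)))
            msg <- c(msg, "truePairs needs columns mirna_id, gene_id")
        else {
            md <- object@mirnaDirection[object@truePairs$mirna_id]
            gd <- object@deStatus[object@truePairs$gene_id, "V1F2"]
            opp <- (md == "up" & gd == "down") | (md == "down" & gd == "up")
            if (!all(opp))
                msg <- c(msg, "truePairs must be sign-opposed in V1F2")
        }
    }
    if (length(msg)) msg else TRUE
})
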