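#' Library sizes of a DGECountSet
#'
#' Total mapped tags per library: the RPKM denominator and the N1/N2 of the
#' Audic-Claverie test.
#'
#' @param object A [DGECountSet-class].
#' @return Named numeric vector, one entry per library.
#' @export
setGeneric("librarySizes", function(object) standardGeneric("librarySizes"))

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "DGECountSet", function(object) {
    ls <- SummarizedExperiment::colData(object)$librarySize
    names(ls) <- colnames(object)
    ls
})

#' Tag counts of a DGECountSet
#'
#' @param object A [DGECountSet-class].
#' @param ... Ignored.
#' @return Gene x library matrix of tag counts.
#' @export
setMethod("counts", "DGECountSet", function(object, ...) {
    SummarizedExperiment::assay(object, "counts")
})

setMethod("show", "DGECountSet", function(object) {
    cat("DGECountSet with", nrow(object), "genes and", ncol(object),
        "libraries\n")
    cat("libraries:", paste(colnames(object), collapse = ", "), "\n")
    cat("library sizes:",
        paste(format(librarySizes(object), big.mark = ",", trim = TRUE),
              collapse = ", "), "tags\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes;",
        paste0(names(object@librarySizes), "=",
               format(object@librarySizes, big.mark = ",", trim = TRUE),
               collapse = " "), "\n")
    cat("  planted DE fractions:",
        paste0(names(object@fracDE), "=", object@fracDE, collapse = " "),
        "; |log2 fold| in [", object@log2FoldRange[1], ",",
        object@log2FoldRange[2], "]\n")
    cat("  miRNAs:", object@nMirnas, "(", object@nNovelMirnas, "novel );",
        "targets/miRNA", object@targetsPerMirna[1], "-",
        object@targetsPerMirna[2], "; opposed fraction",
        object@fracOpposed, "\n")
    cat("  seed:", object@seed, "\n")
})

setMethod("show", "SimTruth", function(object) {
    tab <- apply(object@deStatus, 2, function(s) sum(s != "null"))
    cat("SimTruth for", nrow(object@deStatus), "genes\n")
    cat("  true DE per comparison:",
        paste0(names(tab), "=", tab, collapse = " "), "\n")
    if (length(object@mirnaDirection))
        cat("  miRNAs:", length(object@mirnaDirection), "(",
            sum(object@mirnaDirection == "up"), "up /",
            sum(object@mirnaDirection == "down"), "down );",
            nrow(object@truePairs), "true antagonistic pairs\n")
})
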