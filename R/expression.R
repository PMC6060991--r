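#' Effective gene length under the longest-transcript rule
#'
#' When a gene has several transcripts, its expression level is computed on
#' the longest one.
#'
#' @param lengths Positive numeric vector of transcript lengths (bp) for one
#'   gene.
#' @return The maximum transcript length.
#' @examples
#' effectiveGeneLength(c(500, 1200, 800))  # 1200
#' @export
effectiveGeneLength <- function(lengths) {
    if (!length(lengths))
        stopValidation("gene model must have at least one transcript")
    if (any(!is.finite(lengths)) || any(lengths <= 0))
        stopValidation("transcript lengths must be positive")
    max(lengths)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = 1e9 * C / (N * L)` with `C` the tag count, `N` the library's total
#' mapped tags and `L` the effective gene length in bp. Vectorized.
#'
#' @param count Non-negative tag counts.
#' @param librarySize Positive total mapped tags.
#' @param length Positive effective gene length (bp).
#' @return RPKM values (0 where `count` is 0).
#' @examples
#' rpkm(1000, 1e7, 1000)  # 100
#' @export
rpkm <- function(count, librarySize, length) {
    if (any(count < 0))
        stopValidation("counts must be non-negative")
    if (any(librarySize <= 0))
        stopValidation("library size must be positive")
    if (any(length <= 0))
        stopValidation("gene length must be positive")
    1e9 * count / (librarySize * length)
}

#' RPKM matrix of a DGECountSet
#'
#' Applies [rpkm()] gene-wise using each library's size and the effective
#' (longest-transcript) gene length. Genes absent from the length table are
#' dropped with a warning rather than failing the run; gene and library
#' order are otherwise preserved.
#'
#' @param object A [DGECountSet-class].
#' @param geneLengths Either a named numeric vector of effective lengths or
#'   a data.frame with columns `gene_id` and `length` (bp).
#' @return Numeric matrix of RPKM values (genes x libraries).
#' @export
rpkmMatrix <- function(object, geneLengths) {
    stopifnot(is(object, "DGECountSet"))
    if (is.data.frame(geneLengths)) {
        if (!all(c("gene_id", "length") %in% colnames(geneLengths)))
            stopValidation("gene length table needs columns gene_id, length")
        geneLengths <- stats::setNames(geneLengths$length,
                                       geneLengths$gene_id)
    }
    cts <- counts(object)
    have <- rownames(cts) %in% names(geneLengths)
    if (!all(have)) {
        warning(sum(!have), " gene(s) missing from the gene-length table ",
                "were dropped from the RPKM output")
        cts <- cts[have, , drop = FALSE]
    }
    len <- geneLengths[rownames(cts)]
    ls <- librarySizes(object)
    out <- sweep(cts, 2, ls, FUN = "/")
    out <- sweep(out, 1, len, FUN = "/") * 1e9
    out
}

# Category layout of the sequencing summary table: (column name, label).
mappingCategories <- function() {
    data.frame(
        column = c("total_reads", "total_mapped", "perfect_match",
                   "mismatch_le3", "unique_match", "multi_match",
                   "unmapped"),
        label = c("Total reads", "Total mapped reads", "Perfect match",
                  "<= 3 bp mismatch", "Unique match", "Multi-position match",
                  "Total unmapped reads"),
        stringsAsFactors = FALSE)
}

#' Per-library read-mapping summary percentages
#'
#' Recomputes the sequencing summary arithmetic: each read category as a
#' percentage of total reads, rounded half-up to 2 decimals (so the total
#' row is exactly 100.00). Library statistics must satisfy the additivity
#' identities `unique_match + multi_match = total_mapped`,
#' `perfect_match + mismatch_le3 = total_mapped` and
#' `total_mapped + unmapped = total_reads`; a violated identity raises a
#' validation error naming it.
#'
#' @param stats data.frame with one row per library and columns
#'   `library_id`, `total_reads`, `total_mapped`, `perfect_match`,
#'   `mismatch_le3`, `unique_match`, `multi_match`, `unmapped` (all
#'   non-negative read counts).
#' @param pctOfMapped Also report each mapped sub-category as a percentage
#'   of `total_mapped` (the alternative in-text convention)? Default FALSE.
#' @return Long data.frame: `library_id`, `category`, `reads`, `percent`
#'   (of total reads, 2 decimals), and optionally `pct_of_mapped`.
#' @examples
#' st <- data.frame(library_id = "L1", total_reads = 100, total_mapped = 80,
#'                  perfect_match = 60, mismatch_le3 = 20, unique_match = 70,
#'                  multi_match = 10, unmapped = 20)
#' mappingSummary(st)
#' @export
mappingSummary <- function(stats, pctOfMapped = FALSE) {
    need <- c("library_id", mappingCategories()$column)
    miss <- setdiff(need, colnames(stats))
    if (length(miss))
        stopValidation("missing columns: ", paste(miss, collapse = ", "))
    num <- mappingCategories()$column
    if (any(!is.finite(as.matrix(stats[num]))) || any(stats[num] < 0))
        stopValidation("read counts must be non-negative")
    checkIdentity <- function(lhs, rhs) {
        bad <- stats[[lhs[1]]] + stats[[lhs[2]]] != stats[[rhs]]
        if (any(bad))
            stopValidation("identity ", lhs[1], " + ", lhs[2], " = ", rhs,
                           " violated for library: ",
                           paste(stats$library_id[bad], collapse = ", "))
    }
    checkIdentity(c("unique_match", "multi_match"), "total_mapped")
    checkIdentity(c("perfect_match", "mismatch_le3"), "total_mapped")
    checkIdentity(c("total_mapped", "unmapped"), "total_reads")
    mapped <- c("total_mapped", "perfect_match", "mismatch_le3",
                "unique_match", "multi_match")
    out <- do.call(rbind, lapply(seq_len(nrow(stats)), function(i) {
        row <- stats[i, ]
        reads <- unlist(row[num], use.names = FALSE)
        res <- data.frame(
            library_id = row$library_id,
            category = num,
            reads = reads,
            percent = roundHalfUp(100 * reads / row$total_reads, 2),
            stringsAsFactors = FALSE)
        if (pctOfMapped)
            res$pct_of_mapped <- ifelse(
                num %in% mapped,
                roundHalfUp(100 * reads / row$total_mapped, 2), NA_real_)
        res
    }))
    rownames(out) <- NULL
    out
}
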