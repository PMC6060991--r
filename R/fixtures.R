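# Packaged worked-example tables transcribed from the emulated study's
# printed summary tables.

#' Load a packaged worked-example table
#'
#' Three tables from the emulated wild-rice flowering study ship with the
#' package as plain TSV:
#' \describe{
#'   \item{`table1_stats`}{Sequencing/mapping summary of the three tag
#'     libraries (CWRT-V1, CWRT-V2, CWRT-F2): read counts and printed
#'     percentages per category, long format (8 categories per library).}
#'   \item{`table2_pairs`}{The 28 antagonistic miRNA-mRNA interaction
#'     groups: one row per distinct miRNA with its regulation direction
#'     (flowering over vegetative stage) and its sign-opposed target genes
#'     as a list column, duplicated target entries kept exactly as printed
#'     (the study's own 27/66 target-entry splits count listed entries).
#'     With `long = TRUE`, one row per target entry instead.}
#'   \item{`table3_flowering`}{The flowering-annotated subset of the pairs:
#'     miRNA group, directions, target gene and functional description, one
#'     row per printed target line.}
#' }
#'
#' @param name One of `"table1_stats"`, `"table2_pairs"`,
#'   `"table3_flowering"`.
#' @param long For `table2_pairs` only: return the entry-level table (one
#'   row per miRNA-target entry) instead of the grouped 28-row form.
#' @return A data.frame; directions are normalized to lower case `up`/`down`
#'   (the printed tables mix case), identifiers are kept verbatim.
#' @examples
#' tab2 <- loadFixture("table2_pairs")
#' nrow(tab2)                     # 28
#' tab2$targets[[1]]              # the 8 targets of the first miRNA
#' @export
loadFixture <- function(name, long = FALSE) {
    files <- c(table1_stats = "table1_stats.tsv",
               table2_pairs = "table2_pairs.tsv",
               table3_flowering = "table3_flowering.tsv")
    if (length(name) != 1L || !name %in% names(files))
        stop("unknown fixture '", name, "'; available: ",
             paste(names(files), collapse = ", "), call. = FALSE)
    path <- system.file("extdata", files[[name]],
                        package = "floweringDGE", mustWork = TRUE)
    tab <- readTsv(path)
    if (name == "table1_stats")
        return(tab)
    dirCols <- intersect(c("mirna_direction", "target_direction"),
                         colnames(tab))
    for (cc in dirCols) tab[[cc]] <- tolower(tab[[cc]])
    if (name == "table2_pairs" && !long) {
        grouped <- groupByMirna(data.frame(
            mirna_id = tab$mirna_id,
            mirna_direction = tab$mirna_direction,
            gene_id = tab$target_gene,
            gene_direction = tab$target_direction,
            stringsAsFactors = FALSE))
        grouped$number <- tab$number[match(grouped$mirna_id, tab$mirna_id)]
        return(grouped[, c("number", "mirna_id", "mirna_direction",
                           "targets", "n_targets")])
    }
    tab
}

#' Library statistics of the packaged sequencing summary
#'
#' Reshapes the `table1_stats` fixture into the wide per-library form
#' accepted by [mappingSummary()] (read categories only; the base-pair row
#' is not a read category).
#'
#' @return data.frame with one row per library and the columns required by
#'   [mappingSummary()].
#' @export
fixtureLibraryStats <- function() {
    tab <- loadFixture("table1_stats")
    tab <- tab[tab$category != "total_basepairs", ]
    wide <- stats::reshape(tab[, c("library_id", "category", "reads")],
                           idvar = "library_id", timevar = "category",
                           direction = "wide")
    colnames(wide) <- sub("^reads\\.", "", colnames(wide))
    rownames(wide) <- NULL
    wide
}
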