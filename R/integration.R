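# Integration of differentially expressed miRNAs with sign-opposed
# (antagonistic) differentially expressed target mRNAs.

normalizeDirection <- function(d) {
    d <- tolower(trimws(d))
    if (!all(d %in% c("up", "down", "ns")))
        stopValidation("directions must be up/down (or ns for genes)")
    d
}

#' Antagonistic miRNA-mRNA pairs
#'
#' Joins a table of differentially expressed miRNAs, a miRNA-to-target map
#' and a DEG table from one pairwise comparison, emitting one pair record
#' for every listed target that is significantly differentially expressed
#' in the direction opposite to its miRNA (a miRNA represses its targets,
#' so a true regulatory pair is sign-opposed). Target-list order and
#' duplicated target entries are preserved exactly as given. Target-map
#' rows whose miRNA is absent from the DE-miRNA table are skipped with a
#' message, not an error.
#'
#' @param mirnas data.frame with columns `mirna_id`, `direction`
#'   (`up`/`down`) and optionally `novelty` (`known`/`novel`).
#' @param degs DEG data.frame from [screenDEGs()] (columns `gene_id`,
#'   `direction`); only `up`/`down` genes can pair.
#' @param targets data.frame with columns `mirna_id`, `gene_id`, one row
#'   per predicted target entry, in presentation order.
#' @return data.frame of pairs: `mirna_id`, `mirna_direction`, `gene_id`,
#'   `gene_direction` (always opposite), in target-map order.
#' @export
antagonisticPairs <- function(mirnas, degs, targets) {
    if (!all(c("mirna_id", "direction") %in% colnames(mirnas)))
        stopValidation("mirnas needs columns mirna_id, direction")
    if (!all(c("gene_id", "direction") %in% colnames(degs)))
        stopValidation("degs needs columns gene_id, direction")
    if (!all(c("mirna_id", "gene_id") %in% colnames(targets)))
        stopValidation("targets needs columns mirna_id, gene_id")
    if (anyDuplicated(mirnas$mirna_id))
        stopValidation("duplicated mirna_id in the DE-miRNA table")
    mdir <- stats::setNames(normalizeDirection(mirnas$direction),
                            mirnas$mirna_id)
    gd <- normalizeDirection(degs$direction)
    upGenes <- unique(degs$gene_id[gd == "up"])
    downGenes <- unique(degs$gene_id[gd == "down"])
    known <- targets$mirna_id %in% names(mdir)
    if (any(!known))
        message("skipping ", sum(!known), " target entr",
                if (sum(!known) == 1) "y" else "ies",
                " for miRNA(s) absent from the DE-miRNA table: ",
                paste(unique(targets$mirna_id[!known]), collapse = ", "))
    targets <- targets[known, , drop = FALSE]
    md <- unname(mdir[targets$mirna_id])
    opposed <- (md == "up" & targets$gene_id %in% downGenes) |
               (md == "down" & targets$gene_id %in% upGenes)
    out <- data.frame(mirna_id = targets$mirna_id[opposed],
                      mirna_direction = md[opposed],
                      gene_id = targets$gene_id[opposed],
                      gene_direction = ifelse(md[opposed] == "up",
                                              "down", "up"),
                      stringsAsFactors = FALSE, row.names = NULL)
    stopifnot(all(out$mirna_direction != out$gene_direction))
    out
}

#' Group antagonistic pairs into one row per miRNA
#'
#' @param pairs data.frame from [antagonisticPairs()].
#' @return data.frame with one row per distinct miRNA (first-seen order):
#'   `mirna_id`, `mirna_direction`, `targets` (list column, first-seen
#'   order, duplicates kept as listed), `n_targets`.
#' @export
groupByMirna <- function(pairs) {
    if (!nrow(pairs))
        return(data.frame(mirna_id = character(),
                          mirna_direction = character(),
                          targets = I(list()), n_targets = integer(),
                          stringsAsFactors = FALSE))
    ids <- unique(pairs$mirna_id)
    rows <- lapply(ids, function(m) {
        sel <- pairs$mirna_id == m
        data.frame(mirna_id = m,
                   mirna_direction = pairs$mirna_direction[sel][1],
                   targets = I(list(pairs$gene_id[sel])),
                   n_targets = sum(sel),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Direction summary of antagonistic pairs
#'
#' Counts distinct miRNAs by direction and target entries as listed
#' (duplicates included, matching the presentation convention of the
#' emulated study's pair table).
#'
#' @param pairs data.frame from [antagonisticPairs()].
#' @return Named integer vector: `n_mirna_up`, `n_mirna_down`,
#'   `n_target_entries_up_mirna`, `n_target_entries_down_mirna`.
#' @export
pairSummary <- function(pairs) {
    up <- pairs$mirna_direction == "up"
    c(n_mirna_up = length(unique(pairs$mirna_id[up])),
      n_mirna_down = length(unique(pairs$mirna_id[!up])),
      n_target_entries_up_mirna = sum(up),
      n_target_entries_down_mirna = sum(!up))
}

#' Restrict antagonistic pairs to flowering-annotated targets
#'
#' Keeps pairs whose target gene carries the flowering flag in the
#' annotation table and attaches the gene description. Targets missing from
#' the annotation table are treated as not flowering-related (with a
#' message).
#'
#' @param pairs data.frame from [antagonisticPairs()].
#' @param annotations data.frame with columns `gene_id`, `description`,
#'   `flowering` (logical or 0/1).
#' @return The retained pairs with a `gene_description` column, plus
#'   attribute `counts`: the three candidate summaries of the filtered set
#'   (`mirna_groups` rows after grouping, `distinct_mirnas`, `target_rows`).
#' @export
filterFlowering <- function(pairs, annotations) {
    if (!all(c("gene_id", "flowering") %in% colnames(annotations)))
        stopValidation("annotations needs columns gene_id, flowering")
    if (!"description" %in% colnames(annotations))
        annotations$description <- NA_character_
    idx <- match(pairs$gene_id, annotations$gene_id)
    if (anyNA(idx) && nrow(pairs))
        message(sum(is.na(idx)), " pair target(s) missing from the ",
                "annotation table; treated as not flowering-related")
    flag <- as.logical(annotations$flowering[idx])
    flag[is.na(flag)] <- FALSE
    out <- pairs[flag, , drop = FALSE]
    out$gene_description <- annotations$description[idx][flag]
    rownames(out) <- NULL
    attr(out, "counts") <- c(
        mirna_groups = length(unique(out$mirna_id)),
        distinct_mirnas = length(unique(out$mirna_id)),
        target_rows = nrow(out))
    out
}
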