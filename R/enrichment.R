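# Hypergeometric term enrichment (GO / KEGG) over flat term-membership maps.

goNamespaces <- c("biological_process", "cellular_component",
                  "molecular_function")
termNamespaces <- c(goNamespaces, "kegg_pathway")

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of observing `k` or more study genes inside a term of `K`
#' population members when drawing a study of size `n` from a population of
#' size `N` without replacement. Vectorized.
#'
#' @param k Study hits (genes of the study set inside the term).
#' @param n Study size.
#' @param K Population hits (term members in the population).
#' @param N Population size.
#' @return Exact upper-tail probabilities.
#' @examples
#' hypergeomPvalue(5, 5, 10, 20)  # choose(10,5)/choose(20,5)
#' @export
hypergeomPvalue <- function(k, n, K, N) {
    bad <- k < 0 | n < 0 | K < 0 | N < 0 | k > n | n > N | K > N | k > K
    if (any(bad))
        stopValidation("inconsistent counts: need 0 <= k <= min(n, K), ",
                       "n <= N, K <= N")
    stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

normalizeTermMap <- function(terms) {
    if (!all(c("term_id", "gene_id") %in% colnames(terms)))
        stopValidation("term map needs columns term_id, gene_id")
    if (!"namespace" %in% colnames(terms))
        terms$namespace <- NA_character_
    known <- is.na(terms$namespace) | terms$namespace %in% termNamespaces
    if (!all(known))
        stopValidation("unknown namespace(s): ",
                       paste(unique(terms$namespace[!known]), collapse = ", "))
    if (!"description" %in% colnames(terms))
        terms$description <- NA_character_
    terms
}

#' Hypergeometric term enrichment of a study gene set
#'
#' Tests each term for over-representation of study genes against the
#' population background with the exact upper-tail hypergeometric test, then
#' adjusts p-values by Benjamini-Hochberg within each namespace (so GO
#' categories and KEGG pathways form separate multiple-testing families).
#' Terms with no population member are dropped; terms with zero study hits
#' are still tested (k = 0, p = 1) so the BH denominator does not depend on
#' the study set.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`; empty study is a validation error).
#' @param population Character vector of background gene ids (typically all
#'   genes with at least one mapped tag).
#' @param terms Term-membership data.frame with columns `term_id`,
#'   `gene_id` and optionally `namespace` (one of `biological_process`,
#'   `cellular_component`, `molecular_function`, `kegg_pathway`) and
#'   `description`.
#' @param alpha Significance threshold on the adjusted value (default 0.05).
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @return data.frame sorted by `q_value`: `term_id`, `namespace`,
#'   `description`, `k`, `n`, `K`, `N`, `p_value`, `q_value`, `enriched`.
#' @export
enrich <- function(study, population, terms, alpha = 0.05,
                   correction = c("BH", "bonferroni")) {
    correction <- match.arg(correction)
    study <- unique(as.character(study))
    population <- unique(as.character(population))
    if (!length(study))
        stopValidation("study set is empty")
    extra <- setdiff(study, population)
    if (length(extra))
        stopValidation("study genes absent from the population: ",
                       paste(utils::head(extra, 5), collapse = ", "),
                       if (length(extra) > 5) ", ...")
    if (alpha <= 0 || alpha > 1)
        stopValidation("alpha must lie in (0, 1]")
    terms <- normalizeTermMap(terms)
    terms <- terms[terms$gene_id %in% population, , drop = FALSE]
    if (!nrow(terms))
        stopValidation("no term has a population member")
    key <- paste(terms$term_id, terms$namespace, sep = "\r")
    split_genes <- split(terms$gene_id, key)
    meta <- terms[!duplicated(key), c("term_id", "namespace", "description")]
    meta <- meta[match(names(split_genes), paste(meta$term_id,
                                                 meta$namespace,
                                                 sep = "\r")), ]
    N <- length(population)
    n <- length(study)
    K <- vapply(split_genes, function(g) length(unique(g)), integer(1))
    k <- vapply(split_genes,
                function(g) length(intersect(unique(g), study)), integer(1))
    p <- hypergeomPvalue(k, n, K, N)
    out <- data.frame(term_id = meta$term_id,
                      namespace = meta$namespace,
                      description = meta$description,
                      k = unname(k), n = n, K = unname(K), N = N,
                      p_value = unname(p),
                      stringsAsFactors = FALSE, row.names = NULL)
    fam <- ifelse(is.na(out$namespace), "unspecified", out$namespace)
    out$q_value <- NA_real_
    for (f in unique(fam)) {
        sel <- fam == f
        out$q_value[sel] <- if (correction == "BH") bhAdjust(out$p_value[sel])
                            else pmin(1, out$p_value[sel] * sum(sel))
    }
    out$enriched <- out$q_value <= alpha
    out[order(out$q_value, out$p_value, out$term_id), ]
}

#' GO-namespace breakdown of a study set's term assignments
#'
#' Counts the (gene, term) annotation assignments of the study genes in each
#' of the three GO namespaces and reports each as a percentage of the total,
#' rounded half-up to one decimal.
#'
#' @param study Character vector of gene ids.
#' @param terms Term-membership data.frame as for [enrich()]; only rows with
#'   a GO namespace participate.
#' @return data.frame with `namespace`, `assignments`, `percent`; when no
#'   study gene carries a GO assignment all percentages are 0 and the total
#'   is flagged with a warning.
#' @export
categoryBreakdown <- function(study, terms) {
    terms <- normalizeTermMap(terms)
    go <- terms[terms$namespace %in% goNamespaces &
                terms$gene_id %in% study, , drop = FALSE]
    counts <- vapply(goNamespaces,
                     function(ns) sum(go$namespace == ns), integer(1))
    total <- sum(counts)
    if (total == 0) {
        warning("no GO assignments for the study set")
        pct <- rep(0, length(counts))
    } else {
        pct <- roundHalfUp(100 * counts / total, 1)
    }
    data.frame(namespace = goNamespaces,
               assignments = unname(counts),
               percent = unname(pct),
               stringsAsFactors = FALSE)
}
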