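# Set logic over the three pairwise DEG comparisons (V1F2, V1V2, V2F2).

comparisonLabels <- c("V1F2", "V1V2", "V2F2")

asComparisonSets <- function(sets) {
    if (!is.list(sets))
        stopValidation("comparison sets must be a named list")
    miss <- setdiff(comparisonLabels, names(sets))
    if (length(miss))
        stopValidation("missing comparison set(s): ",
                       paste(miss, collapse = ", "))
    lapply(sets[comparisonLabels], function(s) unique(as.character(s)))
}

#' DEG-set Venn region counts for the three pairwise comparisons
#'
#' Partitions the union of the three DEG gene sets into the seven disjoint
#' Venn regions and counts each.
#'
#' @param sets Named list of gene-id character vectors with elements
#'   `V1F2`, `V1V2`, `V2F2` (one per pairwise comparison; direction is
#'   ignored — a gene differentially expressed in either direction belongs
#'   to the comparison's set).
#' @return Named integer vector over the 7 regions
#'   (`V1F2_only`, `V1V2_only`, `V2F2_only`, `V1F2_V1V2`, `V1F2_V2F2`,
#'   `V1V2_V2F2`, `all`); the values sum to the size of the union.
#' @examples
#' vennCounts(list(V1F2 = c("a", "b"), V1V2 = c("b"), V2F2 = c("b", "c")))
#' @export
vennCounts <- function(sets) {
    s <- asComparisonSets(sets)
    uni <- unique(unlist(s, use.names = FALSE))
    inA <- uni %in% s$V1F2
    inB <- uni %in% s$V1V2
    inC <- uni %in% s$V2F2
    c(V1F2_only = sum(inA & !inB & !inC),
      V1V2_only = sum(!inA & inB & !inC),
      V2F2_only = sum(!inA & !inB & inC),
      V1F2_V1V2 = sum(inA & inB & !inC),
      V1F2_V2F2 = sum(inA & !inB & inC),
      V1V2_V2F2 = sum(!inA & inB & inC),
      all = sum(inA & inB & inC))
}

# Tokenizer + recursive-descent parser for set expressions over the three
# comparison labels. Grammar (left-associative):
#   expr   := term (('|' | '-') term)*
#   term   := factor ('&' factor)*
#   factor := LABEL | '(' expr ')'
# '&' binds tighter than '|' and '-'.
parseSetExpression <- function(text) {
    pos <- 1L
    n <- nchar(text)
    tokens <- list()
    while (pos <= n) {
        ch <- substr(text, pos, pos)
        if (grepl("^\\s$", ch)) {
            pos <- pos + 1L
        } else if (ch %in% c("(", ")", "&", "|", "-")) {
            tokens[[length(tokens) + 1L]] <- list(tok = ch, pos = pos)
            pos <- pos + 1L
        } else {
            rest <- substr(text, pos, n)
            m <- regmatches(rest, regexpr("^[A-Za-z0-9_]+", rest))
            if (!length(m))
                stopValidation("set expression: unexpected character '",
                               ch, "' at position ", pos)
            tokens[[length(tokens) + 1L]] <- list(tok = m, pos = pos)
            pos <- pos + nchar(m)
        }
    }
    i <- 1L
    peek <- function() if (i <= length(tokens)) tokens[[i]]$tok else NA
    take <- function() { t <- tokens[[i]]; i <<- i + 1L; t }
    fail <- function(msg, at) {
        stopValidation("set expression: ", msg, " at position ", at)
    }
    parseExpr <- function() {
        node <- parseTerm()
        while (!is.na(peek()) && peek() %in% c("|", "-")) {
            op <- take()
            rhs <- parseTerm()
            node <- list(op = op$tok, lhs = node, rhs = rhs)
        }
        node
    }
    parseTerm <- function() {
        node <- parseFactor()
        while (!is.na(peek()) && peek() == "&") {
            op <- take()
            rhs <- parseFactor()
            node <- list(op = "&", lhs = node, rhs = rhs)
        }
        node
    }
    parseFactor <- function() {
        if (is.na(peek()))
            fail("unexpected end of expression", nchar(text) + 1L)
        t <- take()
        if (t$tok == "(") {
            node <- parseExpr()
            if (is.na(peek()) || peek() != ")")
                fail("expected ')'", if (is.na(peek())) nchar(text) + 1L
                     else tokens[[i]]$pos)
            take()
            return(node)
        }
        if (t$tok %in% c(")", "&", "|", "-"))
            fail(paste0("unexpected '", t$tok, "'"), t$pos)
        if (!t$tok %in% comparisonLabels)
            fail(paste0("unknown label '", t$tok, "' (expected ",
                        paste(comparisonLabels, collapse = ", "), ")"),
                 t$pos)
        list(label = t$tok)
    }
    root <- parseExpr()
    if (!is.na(peek()))
        fail(paste0("unexpected '", peek(), "'"), tokens[[i]]$pos)
    root
}

evalSetExpression <- function(node, sets) {
    if (!is.null(node$label))
        return(sets[[node$label]])
    lhs <- evalSetExpression(node$lhs, sets)
    rhs <- evalSetExpression(node$rhs, sets)
    switch(node$op,
           "&" = intersect(lhs, rhs),
           "|" = union(lhs, rhs),
           "-" = setdiff(lhs, rhs),
           stopValidation("unknown operator ", node$op))
}

#' Flowering-exclusive gene set from the three comparison DEG sets
#'
#' Evaluates a boolean set expression over the three pairwise comparison
#' DEG sets. The default expression `"(V1F2 & V2F2) - V1V2"` keeps genes
#' differentially expressed against the flowering-stage library from both
#' vegetative baselines while excluding genes that already differ between
#' the two vegetative samples — the reading of "exclusively related to
#' flowering" used throughout this package. Any alternative reading can be
#' supplied as `expression`.
#'
#' @param sets Named list of gene-id vectors `V1F2`, `V1V2`, `V2F2` (as for
#'   [vennCounts()]).
#' @param expression Set expression string over the labels `V1F2`, `V1V2`,
#'   `V2F2` with operators `&` (intersection), `|` (union), `-`
#'   (difference) and parentheses; `&` binds tighter. A malformed
#'   expression raises a parse error reporting the offending position.
#' @return Character vector of gene ids (sorted, unique).
#' @examples
#' sets <- list(V1F2 = c("a", "b", "c"), V1V2 = c("c"), V2F2 = c("b", "c"))
#' floweringExclusiveGenes(sets)  # "b"
#' @export
floweringExclusiveGenes <- function(sets,
                                    expression = "(V1F2 & V2F2) - V1V2") {
    s <- asComparisonSets(sets)
    ast <- parseSetExpression(expression)
    sort(unique(evalSetExpression(ast, s)))
}

#' Gene-id sets of the three comparisons from DEG tables
#'
#' Convenience constructor: extracts the significant gene ids (direction
#' `up` or `down`) of each comparison's DEG table into the named-list form
#' used by [vennCounts()] and [floweringExclusiveGenes()].
#'
#' @param v1f2,v1v2,v2f2 DEG data.frames from [screenDEGs()] for the
#'   V1-vs-F2, V1-vs-V2 and V2-vs-F2 comparisons.
#' @return Named list of three character vectors.
#' @export
comparisonSets <- function(v1f2, v1v2, v2f2) {
    sig <- function(d) unique(d$gene_id[d$direction %in% c("up", "down")])
    list(V1F2 = sig(v1f2), V1V2 = sig(v1v2), V2F2 = sig(v2f2))
}
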