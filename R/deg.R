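#' Audic-Claverie conditional probability P(y | x)
#'
#' Probability of observing `y` tags for a gene in a library of `N2` total
#' tags, conditional on `x` tags observed in a library of `N1` tags, under
#' the null of equal underlying expression:
#' \deqn{P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}.}
#' Evaluated in log space via `lgamma`, so tag totals up to the millions do
#' not overflow. Vectorized over `x` and `y`.
#'
#' @param y,x Non-negative integer tag counts.
#' @param N1,N2 Positive library sizes (total tags) for the `x` and `y`
#'   libraries respectively.
#' @return Probabilities in (0, 1].
#' @examples
#' acProbability(0, 0, 1e6, 1e6)   # 0.5
#' acProbability(2, 2, 1e6, 1e6)   # choose(4,2)/2^5 = 0.1875
#' @export
acProbability <- function(y, x, N1, N2) {
    checkAcArgs(x, y, N1, N2)
    exp(acLogPmf(y, x, N2 / N1))
}

# log P(y|x) with r = N2/N1; equals the log-pmf of a negative binomial with
# size x+1 and success probability 1/(1+r).
acLogPmf <- function(y, x, r) {
    y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r)
}

checkAcArgs <- function(x, y, N1, N2) {
    if (any(x < 0) || any(y < 0))
        stopValidation("tag counts must be non-negative")
    if (any(abs(x - round(x)) > 1e-8) || any(abs(y - round(y)) > 1e-8))
        stopValidation("tag counts must be integers")
    if (any(N1 <= 0) || any(N2 <= 0))
        stopValidation("library sizes must be positive")
    invisible(TRUE)
}

# One-sided tails of the conditional distribution for scalar x, y.
# The tail on the far side of the mode is summed directly in chunks,
# truncated once the running chunk falls 60 nats below the largest term
# seen (truncation error < 1e-20 relative); the near-side tail comes from
# the complement, which is numerically safe because the directly-summed
# tail is the small one.
acTails <- function(x, y, r) {
    mode <- floor(x * r)
    chunk <- 256L
    sumFrom <- function(from, step) {
        tot <- 0
        top <- -Inf
        lo <- from
        repeat {
            ys <- if (step > 0L) lo:(lo + chunk - 1L) else
                seq(lo, max(0L, lo - chunk + 1L))
            lp <- acLogPmf(ys, x, r)
            tot <- tot + sum(exp(lp))
            m <- max(lp)
            top <- max(top, m)
            if (m < top - 60) break
            if (step < 0L && ys[length(ys)] == 0L) break
            lo <- if (step > 0L) lo + chunk else lo - chunk
            if (lo < 0L) break
        }
        tot
    }
    pmfy <- exp(acLogPmf(y, x, r))
    if (y <= mode) {
        lower <- sumFrom(y, -1L)
        upper <- min(1, 1 - lower + pmfy)
        list(lower = lower, upper = upper)
    } else {
        upper <- sumFrom(y, 1L)
        lower <- min(1, 1 - upper + pmfy)
        list(lower = lower, upper = upper)
    }
}

#' Two-sided Audic-Claverie p-value
#'
#' Doubled smaller tail of the conditional distribution of `y` given `x`:
#' `p = min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`. Tails are summed in
#' log space so extreme counts neither overflow nor lose the small tail to
#' cancellation. Vectorized over `x` and `y`.
#'
#' @inheritParams acProbability
#' @return p-values in (0, 1].
#' @examples
#' acPvalueTwoSided(2, 2, 1e6, 1e6)     # 1: both tails >= 0.5
#' acPvalueTwoSided(100, 0, 1e6, 1e6)   # 2/2^101
#' @export
acPvalueTwoSided <- function(x, y, N1, N2) {
    checkAcArgs(x, y, N1, N2)
    n <- max(length(x), length(y), length(N1), length(N2))
    x <- rep_len(x, n); y <- rep_len(y, n)
    N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
    vapply(seq_len(n), function(i) {
        t <- acTails(x[i], y[i], N2[i] / N1[i])
        min(1, 2 * min(t$lower, t$upper))
    }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values (FDR)
#'
#' Step-up adjustment `q(i) = min_{j >= i} p(j) * n / j` over the sorted
#' p-values, capped at 1 and returned in input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values (q-values), same length and order as `p`.
#' @examples
#' bhAdjust(c(0.001, 0.008, 0.039, 0.041))
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stopValidation("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Pseudocounted library-size-normalized log2 expression ratio
#'
#' `log2(((y + pc)/N2) / ((x + pc)/N1))` — finite for all count pairs, zero
#' when the normalized rates agree.
#'
#' @inheritParams acProbability
#' @param pseudocount Positive pseudo-tag added to both counts (default 1).
#' @return log2 ratio of the test library (`y`) over the reference (`x`).
#' @examples
#' log2Ratio(10, 20, 1e6, 1e6)  # log2(21/11)
#' @export
log2Ratio <- function(x, y, N1, N2, pseudocount = 1) {
    checkAcArgs(x, y, N1, N2)
    if (any(pseudocount <= 0))
        stopValidation("pseudocount must be positive")
    log2(((y + pseudocount) / N2) / ((x + pseudocount) / N1))
}

#' Screen differentially expressed genes between two libraries
#'
#' For each gene with at least one tag in either library, computes the
#' Audic-Claverie two-sided p-value, BH-adjusted FDR across tested genes,
#' and the pseudocounted log2 ratio (test over reference), then calls a
#' gene `up`/`down` when `fdr <= fdrMax` and `|log2_ratio| >= absLog2Min`
#' (otherwise `ns`). Genes with zero tags in both libraries carry no
#' information and are excluded before testing.
#'
#' @param object A [DGECountSet-class].
#' @param comparison Character of length 2: reference then test library
#'   label, e.g. `c("V1", "F2")`.
#' @param fdrMax Significance threshold on FDR (default 0.001).
#' @param absLog2Min Minimum absolute log2 ratio (default 1).
#' @param pseudocount Pseudo-tag for the log2 ratio (default 1).
#' @param geneLengths Optional named vector of effective gene lengths (bp);
#'   when given, RPKM columns for both libraries are included.
#' @return data.frame with one row per tested gene: `gene_id`, `comparison`,
#'   `x`, `y`, optional `rpkm_ref`/`rpkm_test`, `log2_ratio`, `p_value`,
#'   `fdr`, `direction`.
#' @examples
#' cts <- matrix(c(100L, 30L, 0L, 100L, 240L, 0L), nrow = 3,
#'               dimnames = list(paste0("g", 1:3), c("V1", "F2")))
#' dge <- DGECountSet(cts, c(V1 = 1e6, F2 = 1e6))
#' screenDEGs(dge, c("V1", "F2"))
#' @export
screenDEGs <- function(object, comparison, fdrMax = 0.001, absLog2Min = 1,
                       pseudocount = 1, geneLengths = NULL) {
    stopifnot(is(object, "DGECountSet"))
    if (length(comparison) != 2L)
        stopValidation("'comparison' must be c(reference, test)")
    missing <- setdiff(comparison, colnames(object))
    if (length(missing))
        stopValidation("unknown library label: ",
                       paste(missing, collapse = ", "))
    if (fdrMax <= 0 || fdrMax > 1)
        stopValidation("fdrMax must lie in (0, 1]")
    if (absLog2Min < 0)
        stopValidation("absLog2Min must be non-negative")
    cts <- counts(object)
    ls <- librarySizes(object)
    ref <- comparison[1]; tst <- comparison[2]
    x <- cts[, ref]; y <- cts[, tst]
    keep <- (x + y) > 0
    x <- x[keep]; y <- y[keep]
    ids <- rownames(cts)[keep]
    N1 <- ls[[ref]]; N2 <- ls[[tst]]
    p <- acPvalueTwoSided(x, y, N1, N2)
    fdr <- bhAdjust(p)
    l2 <- log2Ratio(x, y, N1, N2, pseudocount)
    sig <- fdr <= fdrMax & abs(l2) >= absLog2Min
    direction <- ifelse(!sig, "ns", ifelse(l2 > 0, "up", "down"))
    out <- data.frame(gene_id = ids,
                      comparison = paste0(ref, "-vs-", tst),
                      x = unname(x), y = unname(y),
                      log2_ratio = unname(l2),
                      p_value = unname(p), fdr = unname(fdr),
                      direction = direction,
                      stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(geneLengths)) {
        len <- geneLengths[out$gene_id]
        known <- !is.na(len)
        if (!all(known))
            warning(sum(!known), " gene(s) missing from gene lengths; ",
                    "RPKM reported as NA for them")
        out$rpkm_ref <- ifelse(known, rpkm(out$x, N1, len), NA_real_)
        out$rpkm_test <- ifelse(known, rpkm(out$y, N2, len), NA_real_)
        out <- out[, c("gene_id", "comparison", "x", "y",
                       "rpkm_ref", "rpkm_test",
                       "log2_ratio", "p_value", "fdr", "direction")]
    }
    out
}

#' Count up- and down-regulated genes in a DEG table
#'
#' @param records A data.frame from [screenDEGs()] (needs a `direction`
#'   column).
#' @return Named integer vector `c(n_up, n_down)`.
#' @export
degSummary <- function(records) {
    if (!nrow(records))
        return(c(n_up = 0L, n_down = 0L))
    c(n_up = sum(records$direction == "up"),
      n_down = sum(records$direction == "down"))
}
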