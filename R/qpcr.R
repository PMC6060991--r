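# qRT-PCR validation arithmetic: dilution-series standard curve,
# delta-delta-Ct fold change, qPCR-vs-sequencing concordance.

#' Dilution-series standard curve
#'
#' Least-squares fit of mean CT against log10(input amount) over a serial
#' dilution. The amplification efficiency follows from the slope as
#' `10^(-1/slope) - 1` (1.0 = 100%: a perfect doubling per cycle gives
#' slope -1/log10(2) = -3.3219).
#'
#' @param amounts Positive input amounts (e.g. ng of cDNA), one per dilution
#'   point; at least 3 points are required.
#' @param ct CT values: a numeric vector (one mean CT per point) or a matrix
#'   with one row per dilution point and one column per technical replicate
#'   (replicates are averaged before fitting).
#' @return List with `slope`, `intercept`, `r_squared`, `efficiency`,
#'   `n_points`. A flat series (|slope| below 1e-8) has no defined
#'   efficiency and raises a validation error.
#' @examples
#' amounts <- c(50, 25, 12.5, 6.25, 3.125)
#' standardCurve(amounts, 20 - 3.5 * log10(amounts))
#' @export
standardCurve <- function(amounts, ct) {
    if (any(!is.finite(amounts)) || any(amounts <= 0))
        stopValidation("input amounts must be positive")
    if (is.matrix(ct) || is.data.frame(ct))
        ct <- rowMeans(as.matrix(ct))
    if (length(amounts) != length(ct))
        stopValidation("one CT (or CT row) per dilution point is required")
    if (length(amounts) < 3)
        stopValidation("a standard curve needs at least 3 dilution points")
    fit <- stats::lm(ct ~ log10(amounts))
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || abs(slope) < 1e-8)
        stopValidation("flat dilution series: slope is 0, amplification ",
                       "efficiency is undefined")
    sst <- sum((ct - mean(ct))^2)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sst
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         efficiency = 10^(-1 / slope) - 1,
         n_points = length(amounts))
}

checkMeasurement <- function(m, what) {
    need <- c("target_ct", "reference_ct")
    if (!is.list(m) || !all(need %in% names(m)))
        stopValidation(what, " must be a list with target_ct and ",
                       "reference_ct")
    for (f in need) {
        v <- m[[f]]
        if (!length(v) || any(!is.finite(v)) || any(v <= 0))
            stopValidation(what, "$", f, " must hold at least one ",
                           "positive CT value")
    }
    invisible(TRUE)
}

#' Delta-delta-Ct relative fold change
#'
#' Technical-replicate CTs are averaged, `dCT = mean(target CT) -
#' mean(reference CT)` per sample, `ddCT = dCT(test) - dCT(calibrator)` and
#' the fold change is `2^(-ddCT)` (base-2 amplification). With
#' `efficiency` given, the efficiency-corrected variant
#' `(1 + E)^(-ddCT)` is used instead.
#'
#' @param test,calibrator Measurements: lists with numeric `target_ct` and
#'   `reference_ct` (replicate CT values for the gene of interest and the
#'   internal reference, e.g. OsActin for mRNA or U6 for miRNA).
#' @param efficiency Optional amplification efficiency E (1 = 100%) for the
#'   efficiency-corrected fold change; default uses exact doubling.
#' @return List with `ddct`, `fold_change`, and the per-sample `dct_test`,
#'   `dct_calibrator`.
#' @examples
#' test <- list(target_ct = c(20.1, 20.0, 19.9), reference_ct = rep(15, 3))
#' cal <- list(target_ct = 21, reference_ct = 15)
#' ddctFoldChange(test, cal)$fold_change  # 2
#' @export
ddctFoldChange <- function(test, calibrator, efficiency = NULL) {
    checkMeasurement(test, "test")
    checkMeasurement(calibrator, "calibrator")
    dctT <- mean(test$target_ct) - mean(test$reference_ct)
    dctC <- mean(calibrator$target_ct) - mean(calibrator$reference_ct)
    ddct <- dctT - dctC
    base <- if (is.null(efficiency)) 2 else {
        if (!is.finite(efficiency) || efficiency <= -1)
            stopValidation("efficiency must be > -1")
        1 + efficiency
    }
    list(ddct = ddct,
         fold_change = base^(-ddct),
         dct_test = dctT,
         dct_calibrator = dctC)
}

#' Concordance between qPCR and sequencing fold changes
#'
#' Pearson product-moment correlation between log2 fold changes measured by
#' qRT-PCR and by sequencing over the same genes.
#'
#' @param qpcrLog2Folds,seqLog2Folds Equal-length numeric vectors (>= 3
#'   finite values).
#' @return List with `r`, `n`, and the paired vectors (`qpcr`, `seq`) for
#'   scatter plotting.
#' @export
expressionConcordance <- function(qpcrLog2Folds, seqLog2Folds) {
    if (length(qpcrLog2Folds) != length(seqLog2Folds))
        stopValidation("fold-change vectors must have equal length")
    if (length(qpcrLog2Folds) < 3)
        stopValidation("concordance needs at least 3 genes")
    if (any(!is.finite(qpcrLog2Folds)) || any(!is.finite(seqLog2Folds)))
        stopValidation("fold changes must be finite")
    if (stats::var(qpcrLog2Folds) == 0 || stats::var(seqLog2Folds) == 0)
        stopValidation("zero variance: correlation undefined")
    list(r = stats::cor(qpcrLog2Folds, seqLog2Folds),
         n = length(qpcrLog2Folds),
         qpcr = qpcrLog2Folds,
         seq = seqLog2Folds)
}
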