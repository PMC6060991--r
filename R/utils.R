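# Internal helpers shared across modules.

# Round half away from zero (printed-table convention), rather than R's
# round-half-even. A tiny nudge absorbs binary representation error of
# quotients like 83.145 that decimal arithmetic would place exactly on .5.
roundHalfUp <- function(x, digits = 2) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

readTsv <- function(path, ...) {
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      quote = "", comment.char = "", ...)
}

writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

stopValidation <- function(...) {
    stop(paste0(...), call. = FALSE)
}
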