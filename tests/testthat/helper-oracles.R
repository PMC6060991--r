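# Independent oracles and small constructors shared across tests.

# Brute-force two-sided tag-count test: enumerate the conditional
# distribution P(y'|x) in plain arithmetic via the term recurrence
# t(y')/t(y'-1) = ((x+y')/y') * r/(1+r), far past the observed count, and
# double the smaller tail. Independent of the package's log-space path.
acOracle <- function(x, y, N1, N2, extra = 200L) {
    r <- N2 / N1
    ymax <- x + y + extra
    pmf <- numeric(ymax + 1L)
    pmf[1L] <- (1 / (1 + r))^(x + 1)
    for (yy in seq_len(ymax))
        pmf[yy + 1L] <- pmf[yy] * ((x + yy) / yy) * (r / (1 + r))
    lower <- sum(pmf[seq_len(y + 1L)])
    upper <- sum(pmf[(y + 1L):(ymax + 1L)])
    min(1, 2 * min(lower, upper))
}

# Factorial-ratio upper-tail hypergeometric oracle: direct summation of
# choose() terms.
hgOracle <- function(k, n, K, N) {
    j <- k:min(n, K)
    sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Tiny DGECountSet from a bare matrix.
makeCounts <- function(m, sizes = NULL) {
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- c("V1", "V2", "F2")[seq_len(ncol(m))]
    if (is.null(sizes)) sizes <- rep(1e6, ncol(m))
    DGECountSet(m, stats::setNames(sizes, colnames(m)))
}

# DEG-like table taken straight from simulated truth for one comparison:
# every truly DE gene listed with its true direction (the "all targets pass
# the screen" premise of the pair-recovery checks).
truthDegs <- function(truth, comparison = "V1F2") {
    status <- truth@deStatus[, comparison]
    status[status == "null"] <- "ns"
    data.frame(gene_id = rownames(truth@deStatus),
               direction = unname(status),
               stringsAsFactors = FALSE)
}

# Reconstructed inputs for the integration pipeline from the packaged pair
# table: the printed miRNA directions, the printed target lists, and a DEG
# table assigning each listed target its printed (opposite) direction.
fixtureIntegrationInputs <- function() {
    long <- loadFixture("table2_pairs", long = TRUE)
    mirnas <- unique(long[, c("mirna_id", "mirna_direction")])
    names(mirnas)[2] <- "direction"
    degs <- unique(data.frame(gene_id = long$target_gene,
                              direction = long$target_direction,
                              stringsAsFactors = FALSE))
    targets <- data.frame(mirna_id = long$mirna_id,
                          gene_id = long$target_gene,
                          stringsAsFactors = FALSE)
    list(mirnas = mirnas, degs = degs, targets = targets)
}
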