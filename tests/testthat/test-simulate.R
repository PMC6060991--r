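smallConfig <- function(...) {
    SimConfig(nGenes = 400,
              librarySizes = c(V1 = 1e6, V2 = 1e6, F2 = 1e6),
              ...)
}

test_that("simulation is deterministic given the seed", {
    cfg <- smallConfig(seed = 42L)
    a <- simulateCountLibraries(cfg)
    b <- simulateCountLibraries(cfg)
    expect_identical(counts(a$counts), counts(b$counts))
    expect_identical(a$truth@deStatus, b$truth@deStatus)
    ma <- simulateMirnaTables(cfg, a$truth)
    mb <- simulateMirnaTables(cfg, b$truth)
    expect_identical(ma$targets, mb$targets)
    expect_identical(ma$truth@truePairs, mb$truth@truePairs)
    # different seed, different draw
    c2 <- simulateCountLibraries(smallConfig(seed = 43L))
    expect_false(identical(counts(a$counts), counts(c2$counts)))
})

test_that("null simulation has no planted effects and size-proportional counts", {
    cfg <- SimConfig(nGenes = 2000,
                     librarySizes = c(V1 = 1e6, V2 = 2e6, F2 = 1e6),
                     fracDE = c(V1F2 = 0, V1V2 = 0, V2F2 = 0), seed = 5L)
    sim <- simulateCountLibraries(cfg)
    expect_true(all(sim$truth@deStatus == "null"))
    cts <- counts(sim$counts)
    # aggregate count ratio tracks the library-size ratio (V2 is 2x deeper)
    expect_equal(sum(cts[, "V2"]) / sum(cts[, "V1"]), 2, tolerance = 0.01)
    expect_equal(sum(cts[, "F2"]) / sum(cts[, "V1"]), 1, tolerance = 0.01)
})

test_that("null gene counts match baseline rate x library size", {
    # standardized residuals (count - lambda)/sqrt(lambda) for one fixed
    # gene across 100 independent replicates: mean within 3 sigma of 0
    z <- vapply(1:100, function(s) {
        cfg <- SimConfig(nGenes = 50,
                         librarySizes = c(V1 = 1e6, V2 = 1e6, F2 = 1e6),
                         fracDE = c(V1F2 = 0, V1V2 = 0, V2F2 = 0),
                         seed = 1000L + s)
        sim <- simulateCountLibraries(cfg)
        lam <- sim$truth@baselineRate[25] * 1e6
        (counts(sim$counts)[25, "V1"] - lam) / sqrt(lam)
    }, numeric(1))
    expect_lt(abs(mean(z)), 3 / sqrt(100) * 1.5)
    expect_lt(abs(stats::sd(z) - 1), 0.35)
})

test_that("planted effects are recovered by the downstream screen", {
    cfg <- SimConfig(nGenes = 1000,
                     librarySizes = c(V1 = 1e6, V2 = 1e6, F2 = 1e6),
                     fracDE = c(V1F2 = 0.1, V1V2 = 0.1, V2F2 = 0.1),
                     log2FoldRange = c(1.5, 3), seed = 7L)
    sim <- simulateCountLibraries(cfg)
    deg <- screenDEGs(sim$counts, c("V1", "F2"))
    called <- deg$gene_id[deg$direction != "ns"]
    trueDE <- rownames(sim$truth@deStatus)[
        sim$truth@deStatus[, "V1F2"] != "null"]
    recall <- length(intersect(called, trueDE)) / length(trueDE)
    fdp <- length(setdiff(called, trueDE)) / max(1, length(called))
    expect_gte(recall, 0.8)
    expect_lte(fdp, 0.05)
    # called directions agree with planted directions
    hit <- deg[deg$gene_id %in% trueDE & deg$direction != "ns", ]
    expect_true(all(hit$direction ==
                    sim$truth@deStatus[hit$gene_id, "V1F2"]))
})

test_that("miRNA tables honor the opposed-fraction contract", {
    cfg <- smallConfig(nMirnas = 30L, targetsPerMirna = c(5L, 5L),
                       fracOpposed = 0.6, seed = 9L)
    sim <- simulateCountLibraries(cfg)
    mt <- simulateMirnaTables(cfg, sim$truth)
    expect_equal(nrow(mt$mirnas), 30)
    expect_equal(nrow(mt$targets), 150)
    # pair recovery when every planted target passes the screen
    pairs <- antagonisticPairs(mt$mirnas, truthDegs(mt$truth), mt$targets)
    got <- paste(pairs$mirna_id, pairs$gene_id)
    want <- paste(mt$truth@truePairs$mirna_id, mt$truth@truePairs$gene_id)
    expect_setequal(got, want)  # precision 1, recall 1

    allOpp <- simulateMirnaTables(
        smallConfig(nMirnas = 10L, targetsPerMirna = c(4L, 4L),
                    fracOpposed = 1, seed = 9L), sim$truth)
    p1 <- antagonisticPairs(allOpp$mirnas, truthDegs(allOpp$truth),
                            allOpp$targets)
    expect_equal(nrow(p1), nrow(allOpp$truth@truePairs))
    noneOpp <- simulateMirnaTables(
        smallConfig(nMirnas = 10L, targetsPerMirna = c(4L, 4L),
                    fracOpposed = 0, seed = 9L), sim$truth)
    p0 <- antagonisticPairs(noneOpp$mirnas, truthDegs(noneOpp$truth),
                            noneOpp$targets)
    expect_equal(nrow(p0), 0)
})

test_that("configuration invariants are enforced", {
    expect_error(SimConfig(librarySizes = c(V1 = 0, V2 = 1, F2 = 1)),
                 "positive")
    expect_error(SimConfig(log2FoldRange = c(0.5, 2)), "min >= 1")
    expect_error(SimConfig(fracDE = c(V1F2 = 0.6, V1V2 = 0.3, V2F2 = 0.3)),
                 "sum")
    expect_error(SimConfig(nGenes = 10, targetsPerMirna = c(5L, 20L)),
                 "exceed")
    expect_error(SimConfig(fracOpposed = 1.2), "fracOpposed")
})
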