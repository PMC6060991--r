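test_that("pairing emits exactly the sign-opposed miRNA-target entries", {
    mirnas <- data.frame(mirna_id = c("m1", "m2"),
                         direction = c("up", "down"))
    degs <- data.frame(gene_id = c("gU", "gD", "gN"),
                       direction = c("up", "down", "ns"))
    targets <- data.frame(mirna_id = c("m1", "m1", "m1", "m2", "m2", "m3"),
                          gene_id = c("gD", "gU", "gN", "gU", "gD", "gU"))
    expect_message(p <- antagonisticPairs(mirnas, degs, targets), "m3")
    expect_equal(p$mirna_id, c("m1", "m2"))
    expect_equal(p$gene_id, c("gD", "gU"))
    expect_true(all(p$mirna_direction != p$gene_direction))
})

test_that("grouping and direction summaries behave on simple input", {
    expect_equal(nrow(groupByMirna(data.frame(mirna_id = character(),
                                              mirna_direction = character(),
                                              gene_id = character()))), 0)
    p <- data.frame(mirna_id = c("m1", "m1", "m2"),
                    mirna_direction = c("up", "up", "down"),
                    gene_id = c("g1", "g2", "g3"),
                    gene_direction = c("down", "down", "up"))
    g <- groupByMirna(p)
    expect_equal(nrow(g), 2)
    expect_equal(g$n_targets, c(2L, 1L))
    expect_equal(g$targets[[1]], c("g1", "g2"))
    expect_equal(pairSummary(p),
                 c(n_mirna_up = 1L, n_mirna_down = 1L,
                   n_target_entries_up_mirna = 2L,
                   n_target_entries_down_mirna = 1L))
    one <- p[3, ]
    expect_equal(unname(pairSummary(one)), c(0L, 1L, 0L, 1L))
})

test_that("the packaged pair table re-emerges through the pairing logic", {
    inp <- fixtureIntegrationInputs()
    pairs <- antagonisticPairs(inp$mirnas, inp$degs, inp$targets)
    expect_equal(nrow(pairs), 93)  # every printed target entry is opposed
    grouped <- groupByMirna(pairs)
    expect_equal(nrow(grouped), 28)
    fix <- loadFixture("table2_pairs")
    expect_equal(grouped$mirna_id, fix$mirna_id)
    expect_equal(grouped$mirna_direction, fix$mirna_direction)
    expect_equal(grouped$targets, fix$targets, ignore_attr = TRUE)
    s <- pairSummary(pairs)
    expect_equal(unname(s), c(6L, 22L, 27L, 66L))
})

test_that("duplicate target entries are preserved as listed", {
    fix <- loadFixture("table2_pairs")
    mir390 <- fix$targets[[which(fix$mirna_id == "osa-miR390")]]
    expect_equal(length(mir390), 7)
    expect_equal(sum(mir390 == "LOC_Os02g10100.1"), 2)
})

test_that("flowering filter keeps flagged targets and attaches descriptions", {
    p <- data.frame(mirna_id = c("m1", "m1", "m2"),
                    mirna_direction = c("up", "up", "down"),
                    gene_id = c("g1", "g2", "g3"),
                    gene_direction = c("down", "down", "up"))
    ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                      description = c("d1", "d2", "d3"),
                      flowering = c(TRUE, FALSE, TRUE))
    f <- filterFlowering(p, ann)
    expect_equal(f$gene_id, c("g1", "g3"))
    expect_equal(f$gene_description, c("d1", "d3"))
    noneFlag <- ann; noneFlag$flowering <- FALSE
    expect_equal(nrow(filterFlowering(p, noneFlag)), 0)
    allFlag <- ann; allFlag$flowering <- TRUE
    expect_equal(filterFlowering(p, allFlag)$gene_id, p$gene_id)
    # unannotated target treated as not flowering, with a message
    expect_message(f2 <- filterFlowering(p, ann[1:2, ]), "missing")
    expect_equal(f2$gene_id, "g1")
})

test_that("simulated flowering annotation retains the expected fraction", {
    cfg <- SimConfig(nGenes = 800,
                     librarySizes = c(V1 = 1e6, V2 = 1e6, F2 = 1e6),
                     nMirnas = 40L, targetsPerMirna = c(4L, 8L),
                     fracFloweringAnnotated = 0.3, seed = 31L)
    sim <- simulateCountLibraries(cfg)
    props <- vapply(1:5, function(s) {
        cfg2 <- SimConfig(nGenes = 800,
                          librarySizes = c(V1 = 1e6, V2 = 1e6, F2 = 1e6),
                          nMirnas = 40L, targetsPerMirna = c(4L, 8L),
                          fracFloweringAnnotated = 0.3, seed = 31L + s)
        mt <- simulateMirnaTables(cfg2, sim$truth)
        pairs <- antagonisticPairs(mt$mirnas, truthDegs(mt$truth),
                                   mt$targets)
        kept <- filterFlowering(pairs, mt$annotations)
        nrow(kept) / nrow(pairs)
    }, numeric(1))
    n <- 40 * 6 * 0.6  # rough pair count per replicate
    expect_lt(abs(mean(props) - 0.3), 4 * sqrt(0.3 * 0.7 / (5 * n)))
})
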