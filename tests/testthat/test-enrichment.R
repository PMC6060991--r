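test_that("hypergeometric upper tail matches closed forms", {
    expect_equal(hypergeomPvalue(0, 5, 10, 20), 1)
    expect_equal(hypergeomPvalue(5, 5, 10, 20), choose(10, 5) / choose(20, 5))
    expect_equal(hypergeomPvalue(3, 8, 20, 20), 1)  # K = N
    expect_error(hypergeomPvalue(6, 5, 10, 20), "inconsistent")
    expect_error(hypergeomPvalue(2, 5, 10, 8), "inconsistent")
})

test_that("hypergeometric tail equals the factorial-ratio oracle", {
    set.seed(21)
    for (N in c(15, 40, 120, 200)) {
        for (rep in 1:6) {
            n <- sample(1:N, 1)
            K <- sample(1:N, 1)
            for (k in 0:min(n, K))
                expect_equal(hypergeomPvalue(k, n, K, N),
                             hgOracle(k, n, K, N), tolerance = 1e-12)
        }
    }
    # monotone non-increasing in k
    p <- vapply(0:10, function(k) hypergeomPvalue(k, 10, 30, 100),
                numeric(1))
    expect_true(all(diff(p) <= 1e-15))
})

makeTerms <- function(pop, nTerms = 8, seed = 4) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(nTerms), function(i)
        data.frame(term_id = sprintf("T%02d", i),
                   gene_id = sample(pop, sample(5:30, 1)),
                   namespace = c("biological_process", "cellular_component",
                                 "molecular_function",
                                 "kegg_pathway")[(i - 1) %% 4 + 1],
                   stringsAsFactors = FALSE)))
}

test_that("enrich flags a planted term and nothing when study = population", {
    pop <- sprintf("g%04d", 1:1000)
    terms <- makeTerms(pop)
    planted <- data.frame(term_id = "PLANT", gene_id = pop[1:10],
                          namespace = "biological_process")
    res <- enrich(pop[1:10], pop, rbind(terms, planted))
    row <- res[res$term_id == "PLANT", ]
    expect_lt(row$p_value, 1e-15)
    expect_true(row$enriched)
    # whole population as study: k/n = K/N for every term, nothing enriched
    res2 <- enrich(pop, pop, terms)
    expect_false(any(res2$enriched))
    expect_true(all(res2$p_value == 1))  # k = K when n = N
})

test_that("enrich validates inputs and is order-invariant", {
    pop <- sprintf("g%04d", 1:300)
    terms <- makeTerms(pop)
    expect_error(enrich(character(), pop, terms), "empty")
    expect_error(enrich(c(pop[1:3], "alien1"), pop, terms), "alien1")
    a <- enrich(pop[1:20], pop, terms)
    b <- enrich(rev(pop[1:20]), sample(pop), terms)
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$term_id, b$term_id)
    # zero-hit terms are still tested with p = 1
    lonely <- data.frame(term_id = "ZERO", gene_id = pop[250:260],
                         namespace = "kegg_pathway")
    r <- enrich(pop[1:20], pop, rbind(terms, lonely))
    expect_true("ZERO" %in% r$term_id)
    expect_equal(r$p_value[r$term_id == "ZERO"], 1)
    # bonferroni variant never beats BH
    rb <- enrich(pop[1:20], pop, terms, correction = "bonferroni")
    expect_true(all(rb$q_value >= a$q_value - 1e-15))
})

test_that("category breakdown mirrors assignment arithmetic", {
    study <- sprintf("s%03d", 1:1000)
    terms <- data.frame(
        term_id = rep(c("bp", "cc", "mf"), c(458, 315, 227)),
        gene_id = study,
        namespace = rep(c("biological_process", "cellular_component",
                          "molecular_function"), c(458, 315, 227)))
    br <- categoryBreakdown(study, terms)
    expect_equal(br$percent, c(45.8, 31.5, 22.7))
    expect_equal(sum(br$assignments), 1000)

    only_bp <- terms[terms$namespace == "biological_process", ]
    br2 <- categoryBreakdown(study, only_bp)
    expect_equal(br2$percent, c(100, 0, 0))

    expect_warning(br3 <- categoryBreakdown("nothere", terms),
                   "no GO assignments")
    expect_true(all(br3$percent == 0))
})
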