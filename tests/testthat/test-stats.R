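test_that("hypergeometric enrichment matches exhaustive enumeration", {
    # worked example: N = 20, |A| = 5, |B| = 8, overlap = 4
    res <- hypergeometricEnrichment(letters[1:5], letters[c(1:4, 6:9)],
                                    letters[1:20])
    expect_equal(res$expected, 2.0)
    expect_equal(res$fold, 2.0)
    expect_equal(res$p_value, oracleHyperP(20, 5, 8, 4))

    # maximal overlap: fold = N / |A|
    u <- letters[1:12]
    same <- hypergeometricEnrichment(u[1:4], u[1:4], u)
    expect_equal(same$fold, 12 / 4)
    # disjoint sets: fold 0
    expect_equal(hypergeometricEnrichment(u[1:3], u[4:6], u)$fold, 0)
    expect_error(hypergeometricEnrichment(character(0), u[1:3], u), "empty")

    # enumeration oracle across random instances with N <= 25
    set.seed(61)
    for (i in 1:30) {
        N <- sample(8:25, 1)
        uni <- paste0("g", seq_len(N))
        a <- sample(uni, sample(2:(N - 2), 1))
        b <- sample(uni, sample(2:(N - 2), 1))
        res <- hypergeometricEnrichment(a, b, uni)
        expect_equal(res$p_value,
                     oracleHyperP(N, length(a), length(b), res$n_overlap),
                     tolerance = 1e-12)
    }
})

test_that("Mann-Whitney exact branch equals labeling enumeration", {
    res <- mannWhitney(c(1, 2), c(3, 4))
    expect_equal(res$U, 0)
    expect_equal(res$p_value, 1 / 3)

    set.seed(71)
    for (i in 1:25) {
        nx <- sample(2:5, 1); ny <- sample(2:5, 1)
        if (nx + ny > 10) next
        vals <- sample(1:100, nx + ny) # tie-free
        x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
        expect_equal(mannWhitney(x, y)$p_value, oracleMannWhitneyP(x, y),
                     tolerance = 1e-12)
    }
    # identical samples: p = 1 within tolerance (tied large-sample branch)
    z <- rep(c(1, 2, 3, 4, 5), 4)
    expect_gte(mannWhitney(z, z)$p_value, 0.95)
    expect_error(mannWhitney(numeric(0), 1:3), "empty")
})

test_that("chi-square up/down asymmetry matches the Pearson oracle", {
    res <- chisqUpDown(30, 10)
    expect_equal(res$chi2, 10)
    expect_equal(chisqUpDown(25, 25)$chi2, 0)
    expect_equal(chisqUpDown(25, 25)$p_value, 1)
    # generic Pearson implementation on the 1x2 table as oracle
    oracle <- suppressWarnings(chisq.test(c(30, 10), p = c(0.5, 0.5),
                                          correct = FALSE))
    expect_equal(res$chi2, unname(oracle$statistic))
    expect_equal(res$p_value, oracle$p.value)
    expect_error(chisqUpDown(0, 0))
})

test_that("bonferroni uses the fixed family size and preserves order", {
    expect_equal(bonferroni(0.01, 6), 0.06)
    expect_equal(bonferroni(0.5, 6), 1.0)
    p <- c(0.001, 0.02, 0.3, 0.9)
    expect_identical(order(bonferroni(p, 6)), order(p))
    expect_error(bonferroni(0.1, 0))
})

test_that("ANCOVA marginal means reproduce cell-mean arithmetic", {
    # balanced cells with means (-,-) = 2, (+,-) = 4, (-,+) = 1, (+,+) = 3
    ids <- paste0("g", 1:8)
    expr <- setNames(c(2, 2, 4, 4, 1, 1, 3, 3), ids)
    h2 <- setNames(c(F, F, T, T, F, F, T, T), ids)
    k27 <- setNames(c(F, F, F, F, T, T, T, T), ids)
    res <- suppressWarnings(ancovaEmm(expr, h2, k27))
    emm <- res$emm
    expect_equal(emm$emm[emm$factor == "h2aub" & emm$level == "present"], 3.5)
    expect_equal(emm$emm[emm$factor == "h2aub" & emm$level == "absent"], 1.5)
    expect_equal(emm$emm[emm$factor == "k27" & emm$level == "present"], 2.0)
    expect_equal(emm$emm[emm$factor == "k27" & emm$level == "absent"], 3.0)
    expect_equal(nrow(res$posthoc), 6) # all pairwise cell contrasts

    # no k27 effect: marginal means equal the raw group means
    expr2 <- setNames(c(2, 2, 4, 4, 2, 2, 4, 4), ids)
    res2 <- suppressWarnings(ancovaEmm(expr2, h2, k27))
    emm2 <- res2$emm
    expect_equal(emm2$emm[emm2$factor == "h2aub" & emm2$level == "present"],
                 mean(expr2[h2]))

    # planted additive effects are recovered
    set.seed(81)
    n <- 400
    ids3 <- paste0("g", seq_len(n))
    h3 <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), ids3)
    k3 <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), ids3)
    expr3 <- setNames(5 + 3 * h3 - 2 * k3 + rnorm(n, 0, 0.5), ids3)
    res3 <- ancovaEmm(expr3, h3, k3)
    emm3 <- res3$emm
    dH <- diff(emm3$emm[emm3$factor == "h2aub"]) # present - absent
    dK <- diff(emm3$emm[emm3$factor == "k27"])
    expect_lt(abs(dH - 3), 0.2)
    expect_lt(abs(dK - (-2)), 0.2)
})

test_that("deFilter applies the log2FC / adjusted-p / CPM thresholds", {
    rec <- data.frame(
        gene_id = paste0("g", 1:6),
        log2FC = c(1.2, -0.5, -2.0, 4.5, 1.5, 2.0),
        p_adj = c(0.01, 0.001, 0.04, 0.02, 0.2, 0.01),
        cpm_pass = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
    res <- deFilter(rec)
    expect_setequal(res$up, c("g1", "g4"))
    expect_setequal(res$down, "g3")
    expect_length(intersect(res$up, res$down), 0)
    # stricter cutoff selects a subset
    res4 <- deFilter(rec, lfcCutoff = 4)
    expect_true(all(res4$up %in% res$up))
    expect_setequal(res4$up, "g4")
    expect_error(deFilter(rec, lfcCutoff = 0))
})

test_that("responsiveness medians detect a planted H2Aub1 shift", {
    set.seed(91)
    n <- 200
    ids <- paste0("g", seq_len(n))
    h2 <- setNames(rep(c(TRUE, FALSE), each = n / 2), ids)
    k27 <- setNames(rep(FALSE, n), ids)
    tab <- categorizeMarks(h2, k27)
    scores <- setNames(rpois(n, 50 + 40 * h2), ids)
    res <- suppressWarnings(responsivenessByCategory(scores, tab))
    med <- res$medians
    expect_gt(med$median[med$category == "h2aub_only"],
              med$median[med$category == "not_marked"])
    tst <- res$tests
    expect_lt(tst$p_adj[tst$group1 == "not_marked" &
                        tst$group2 == "h2aub_only"], 0.05)

    # all scores equal: medians equal, p = 1
    flat <- setNames(rep(7, n), ids)
    resF <- suppressWarnings(responsivenessByCategory(flat, tab))
    expect_equal(unique(resF$medians$median), 7)
    expect_true(all(resF$tests$p_adj == 1))

    # genes without scores are excluded
    resPart <- suppressWarnings(
        responsivenessByCategory(scores[1:150], tab))
    expect_equal(sum(resPart$medians$n), 150)
})
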