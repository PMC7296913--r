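test_that("computeMA applies the pseudocounted log-ratio transform", {
    eq <- computeMA(7, 7)
    expect_equal(eq$M, 0)
    expect_equal(computeMA(15, 3)$M, log2(15.5 / 3.5))
    # antisymmetry: swapping samples negates M and preserves A
    ab <- computeMA(12, 3); ba <- computeMA(3, 12)
    expect_equal(ab$M, -ba$M)
    expect_equal(ab$A, ba$A)
    expect_error(computeMA(-1, 2))
})

test_that("fitNormalization recovers degenerate and collinear fits exactly", {
    mkCat <- function(A, M, origin = "common") {
        gr <- gr1(seq(1, by = 2000, length.out = length(A)),
                  seq(1, by = 2000, length.out = length(A)) + 500)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            count_a = 0, count_b = 0, origin = origin, M = M, A = A)
        gr
    }
    # M identically zero: intercept 0, slope 0
    fit0 <- fitNormalization(mkCat(1:10, rep(0, 10)), nSimulations = 0)
    expect_equal(unname(fit0), c(0, 0))
    # exact collinear points (A, M) = (1,1), (2,2), (3,3): M = 0 + 1*A
    fit1 <- fitNormalization(mkCat(1:3, 1:3), nSimulations = 0)
    expect_equal(unname(fit1), c(0, 1), tolerance = 1e-8)
    expect_error(fitNormalization(mkCat(1, 1), nSimulations = 0), "common")
})

test_that("fitNormalization recovers a planted global log2 ratio", {
    set.seed(101)
    r <- 2
    n <- 2000
    lam <- rlnorm(n, log(300), 0.8)
    a <- rpois(n, r * lam); b <- rpois(n, lam)
    gr <- gr1(seq(1, by = 2000, length.out = n),
              seq(1, by = 2000, length.out = n) + 500)
    ma <- computeMA(a, b)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        count_a = a, count_b = b, origin = "common", M = ma$M, A = ma$A)
    fit <- fitNormalization(gr, nSimulations = 100)
    expect_lt(abs(fit[["intercept"]] - log2(r)), 0.1)
    expect_lt(abs(fit[["slope"]]), 0.05)
})

test_that("normalizeAndTest computes exact binomial symmetry p-values", {
    mkCat <- function(a, b) {
        ma <- computeMA(a, b)
        gr <- gr1(seq(1, by = 2000, length.out = length(a)),
                  seq(1, by = 2000, length.out = length(a)) + 500)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            count_a = a, count_b = b, origin = "common", M = ma$M, A = ma$A)
        gr
    }
    identityFit <- c(intercept = 0, slope = 0)

    # identity fit leaves M unchanged
    tested <- normalizeAndTest(mkCat(c(10, 40), c(20, 10)), identityFit)
    expect_equal(tested$M_norm, tested$M)

    # equal rescaled counts: p = 1, fails
    eq <- normalizeAndTest(mkCat(8, 8), identityFit)
    expect_equal(eq$p_value, 1)
    expect_false(eq$significant)

    # 10 vs 0: p = 2 * P(X >= 10 | n = 10, p = .5) = 2/1024
    extreme <- normalizeAndTest(mkCat(10, 0), identityFit)
    expect_equal(extreme$p_value, 2 / 1024)
    expect_equal(extreme$direction, "up")

    # exchanging samples maps up to down and leaves p-values invariant
    a <- c(50, 5, 30); b <- c(10, 25, 30)
    fwd <- normalizeAndTest(mkCat(a, b), identityFit)
    rev <- normalizeAndTest(mkCat(b, a), identityFit)
    expect_equal(fwd$p_value, rev$p_value)
    expect_identical(fwd$direction[fwd$significant],
                     c("down", "up")[match(rev$direction[rev$significant],
                                           c("up", "down"))])
    # p-values live in (0, 1]
    expect_true(all(fwd$p_value > 0 & fwd$p_value <= 1))
})

test_that("null M-A simulation holds its nominal type-I error", {
    set.seed(202)
    n <- 1000
    lam <- rlnorm(n, log(500), 0.5)
    a <- rpois(n, lam); b <- rpois(n, lam)
    gr <- gr1(seq(1, by = 2000, length.out = n),
              seq(1, by = 2000, length.out = n) + 500)
    ma <- computeMA(a, b)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        count_a = a, count_b = b, origin = "common", M = ma$M, A = ma$A)
    tested <- normalizeAndTest(gr, fitNormalization(gr, nSimulations = 0))
    frac <- mean(tested$p_value < 0.05)
    se <- sqrt(0.05 * 0.95 / n)
    expect_lt(abs(frac - 0.05), 3 * se + 0.01) # single-run Monte-Carlo slack
})

test_that("concordantDifferentialPeaks requires same-direction overlap", {
    up1 <- gr1(101, 200); up1$direction <- "up"
    up2 <- gr1(151, 260); up2$direction <- "up"
    conc <- concordantDifferentialPeaks(up1, up2)
    expect_equal(start(conc), 101)
    expect_equal(end(conc), 260)
    expect_equal(conc$direction, "up")

    # same locus, opposite directions: dropped
    down2 <- gr1(151, 260); down2$direction <- "down"
    expect_length(concordantDifferentialPeaks(up1, down2), 0)
    # empty replicate: empty result
    empty <- GRanges(); empty$direction <- character(0)
    expect_length(concordantDifferentialPeaks(up1, empty), 0)
})

test_that("defineUbpTargets applies the gain-minus-loss subtraction rule", {
    genes <- gr1(c(1001, 8001, 16001), c(4000, 11000, 19000), strand = "+")
    genes$gene_id <- c("gA", "gB", "gC")
    up <- gr1(c(1101, 8101), c(1300, 8300))     # gA and gB gain
    down <- gr1(8201, 8400)                      # gB also loses: excluded
    expect_identical(defineUbpTargets(up, down, genes), "gA")
    expect_identical(defineUbpTargets(up, GRanges(), genes), c("gA", "gB"))
    expect_length(defineUbpTargets(GRanges(), down, genes), 0)
})

test_that("planted targets are recovered from the synthetic study", {
    fx <- getStudy()
    reps <- lapply(1:2, function(r) {
        differentialPeaks(fx$peaks[[sprintf("H2Aub1_mutant_rep%d", r)]],
                          fx$peaks[[sprintf("H2Aub1_wt_rep%d", r)]],
                          fx$libraries[[sprintf("H2Aub1_mutant_rep%d", r)]],
                          fx$libraries[[sprintf("H2Aub1_wt_rep%d", r)]])
    })
    conc <- concordantDifferentialPeaks(reps[[1]], reps[[2]])
    targets <- defineUbpTargets(conc[conc$direction == "up"],
                                conc[conc$direction == "down"], fx$genes)
    truth <- fx$groundTruth$target_genes
    expect_gte(length(intersect(targets, truth)) / length(truth), 0.9)
    expect_gte(length(intersect(targets, truth)) / length(targets), 0.9)
    # planted losses surface as concordant down peaks on their first 1 kb
    downG <- genesWithPeak(conc[conc$direction == "down"], fx$genes)
    expect_true(all(fx$groundTruth$loss_genes %in% names(downG)[downG]))
})
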