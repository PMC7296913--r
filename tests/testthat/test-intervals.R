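# gene bodies below are given as GRanges (1-based, closed); the classic
# half-open example [1000, 3000) is GRanges 1001-3000

test_that("deriveRegion extracts strand-aware gene regions", {
    plus <- gr1(1001, 3000, strand = "+")
    minus <- gr1(1001, 3000, strand = "-")

    expect_equal(ranges(deriveRegion(plus, "first_1kb")), IRanges(1001, 2000))
    # minus strand: "first" measured from the high-coordinate end; checked
    # by reflecting coordinates and applying the plus-strand rule
    L <- 4000L
    reflectedPlus <- gr1(L - 3000 + 1, L - 1001 + 1, strand = "+")
    refl <- deriveRegion(reflectedPlus, "first_1kb")
    expect_equal(ranges(deriveRegion(minus, "first_1kb")),
                 IRanges(L - end(refl) + 1, L - start(refl) + 1))
    expect_equal(ranges(deriveRegion(minus, "first_1kb")), IRanges(2001, 3000))

    # truncation: a gene shorter than 1 kb contributes its whole body
    short <- gr1(1001, 1500, strand = "+")
    expect_equal(ranges(deriveRegion(short, "first_1kb")), IRanges(1001, 1500))

    # 20% regions: floor(2000 * 0.2) = 400 bp from the relevant end
    expect_equal(ranges(deriveRegion(plus, "last_20pct")), IRanges(2601, 3000))
    expect_equal(ranges(deriveRegion(plus, "first_20pct")), IRanges(1001, 1400))
    expect_equal(ranges(deriveRegion(minus, "last_20pct")), IRanges(1001, 1400))

    expect_equal(ranges(deriveRegion(plus, "upstream_2kb")), IRanges(1, 1000))
    expect_equal(ranges(deriveRegion(plus, "genic")), IRanges(1, 3000))
    expect_error(deriveRegion(plus, "nonsense"))
})

test_that("derived regions stay within body plus upstream and chromosome bounds", {
    set.seed(42)
    for (i in 1:50) {
        s <- sample(1:5000, 1)
        w <- sample(200:4000, 1)
        st <- sample(c("+", "-"), 1)
        g <- GRanges("chr1", IRanges(s, width = w), strand = st,
                     seqlengths = c(chr1 = 10000L))
        genic <- deriveRegion(g, "genic")
        for (kind in c("first_1kb", "first_20pct", "last_20pct", "upstream_2kb")) {
            r <- deriveRegion(g, kind)
            expect_gte(start(r), 1L)
            expect_lte(end(r), 10000L)
            expect_gte(start(r), start(genic))
            expect_lte(end(r), end(genic))
        }
    }
})

test_that("mergeIntervals gives the minimal disjoint cover", {
    expect_equal(ranges(mergeIntervals(gr1(c(1, 6), c(10, 20)))),
                 IRanges(1, 20))
    expect_length(mergeIntervals(GRanges()), 0)

    set.seed(7)
    for (i in 1:20) {
        n <- sample(5:100, 1)
        s <- sample(1:2000, n, replace = TRUE)
        e <- s + sample(1:300, n, replace = TRUE)
        merged <- mergeIntervals(gr1(s, e))
        oracle <- oracleMergeMask(s, e)
        expect_equal(start(merged), oracle$start)
        expect_equal(end(merged), oracle$end)
        # idempotence
        expect_identical(ranges(mergeIntervals(merged)), ranges(merged))
    }
})

test_that("intersectReplicates keeps and merges cross-replicate overlaps", {
    # [100,200) + [500,600) vs [150,250): only the first pair overlaps
    r1 <- gr1(c(101, 501), c(200, 600))
    r2 <- gr1(151, 250)
    expect_equal(ranges(intersectReplicates(r1, r2)), IRanges(101, 250))

    expect_length(intersectReplicates(r1, GRanges()), 0)
    same <- gr1(1, 100)
    expect_equal(ranges(intersectReplicates(same, same)), IRanges(1, 100))

    # chromosome mismatch is plain non-overlap
    expect_length(intersectReplicates(gr1(1, 100, chrom = "chr1"),
                                      gr1(1, 100, chrom = "chr2")), 0)

    # symmetry and agreement with an all-pairs oracle on random instances
    set.seed(11)
    for (i in 1:20) {
        a <- gr1(s <- sample(1:5000, 30), s + sample(50:400, 30, replace = TRUE))
        b <- gr1(s2 <- sample(1:5000, 25), s2 + sample(50:400, 25, replace = TRUE))
        ab <- intersectReplicates(a, b)
        ba <- intersectReplicates(b, a)
        expect_identical(ranges(ab), ranges(ba))
        ov <- oracleOverlaps(start(a), end(a), start(b), end(b))
        kept <- c(start(a)[rowSums(ov) > 0], start(b)[colSums(ov) > 0])
        keptE <- c(end(a)[rowSums(ov) > 0], end(b)[colSums(ov) > 0])
        if (length(kept)) {
            oracle <- oracleMergeMask(kept, keptE)
            expect_equal(start(ab), oracle$start)
            expect_equal(end(ab), oracle$end)
        } else {
            expect_length(ab, 0)
        }
    }
})

test_that("annotatePeaksToGenes maps peaks to first-kilobase overlaps", {
    g <- gr1(1001, 3000, strand = "+")
    g$gene_id <- "geneA"
    inside <- gr1(1201, 1400)
    outside <- gr1(2501, 2600) # in the body but beyond the first 1 kb
    ann <- annotatePeaksToGenes(c(inside, outside), g)
    expect_length(ann[["geneA"]], 1)
    expect_equal(start(ann[["geneA"]]), 1201)

    # genes with no peaks are present with empty entries
    g2 <- gr1(c(1001, 8001), c(3000, 9000), strand = "+")
    g2$gene_id <- c("geneA", "geneB")
    ann2 <- annotatePeaksToGenes(inside, g2)
    expect_named(ann2, c("geneA", "geneB"))
    expect_length(ann2[["geneB"]], 0)

    # random instances agree with an all-pairs overlap oracle
    set.seed(3)
    for (i in 1:10) {
        gs <- sample(seq(1, 40000, by = 4000))
        genes <- gr1(gs, gs + 2999, strand = sample(c("+", "-"), 10, replace = TRUE))
        genes$gene_id <- paste0("g", seq_along(genes))
        ps <- sample(1:42000, 40)
        peaks <- gr1(ps, ps + sample(100:900, 40, replace = TRUE))
        ann <- annotatePeaksToGenes(peaks, genes)
        reg <- deriveRegion(genes, "first_1kb")
        ov <- oracleOverlaps(start(reg), end(reg), start(peaks), end(peaks))
        for (k in seq_along(genes))
            expect_length(ann[[genes$gene_id[k]]], sum(ov[k, ]))
    }
})
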