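test_that("scanMotifs finds degenerate 8-mers on both strands", {
    # forward hit at 0-based position 2 (1-based 3)
    h <- scanMotifs("AACTCTGCTCAA")
    expect_equal(start(h), 3)
    expect_equal(as.character(strand(h)), "+")
    # A at a Y position: no hit
    expect_length(scanMotifs("CTCTGATC"), 0)
    # N never matches
    expect_length(scanMotifs("CTCTGNTC"), 0)
    # reverse-strand hit: reverse complement of CTCTGCTC is GAGCAGAG
    hr <- scanMotifs("TTGAGCAGAGTT")
    expect_equal(start(hr), 3)
    expect_equal(as.character(strand(hr)), "-")
})

test_that("scanMotifs equals the naive sliding-window oracle", {
    set.seed(21)
    for (i in 1:8) {
        # motif-rich random sequence (boosted C/T content)
        seqchar <- paste(sample(c("A", "C", "G", "T", "C", "T"), 10000,
                                replace = TRUE), collapse = "")
        hits <- scanMotifs(Biostrings::DNAStringSet(c(chr1 = seqchar)))
        oracle <- oracleScanMotif(seqchar)
        key <- function(s, st) paste(s, st)
        expect_setequal(key(start(hits), as.character(strand(hits))),
                        key(oracle$start, oracle$strand))
    }
})

test_that("findMotifClusters detects maximal runs within the window", {
    # 0-based starts 0,100,300,550: span 558 fits 600 -> one cluster, n = 4
    hits <- gr1(c(1, 101, 301, 551), c(8, 108, 308, 558))
    cl <- findMotifClusters(hits)
    expect_length(cl, 1)
    expect_equal(start(cl), 1)
    expect_equal(end(cl), 558)
    expect_equal(cl$n_motifs, 4L)
    # three hits only: below the minimum
    expect_length(findMotifClusters(hits[1:3]), 0)
    # span just over the window: no cluster
    wide <- gr1(c(1, 200, 400, 594), c(8, 207, 407, 601))
    expect_length(findMotifClusters(wide), 0)
})

test_that("findMotifClusters agrees with the brute-force window oracle", {
    set.seed(31)
    for (i in 1:15) {
        n <- sample(10:60, 1)
        starts <- sort(sample(1:8000, n))
        hits <- gr1(starts, starts + 7L)
        cl <- findMotifClusters(hits)
        oracle <- oracleClusters(starts)
        expect_equal(start(cl), oracle$start)
        expect_equal(end(cl), oracle$end)
        # merged recount never violates the minimum
        if (length(cl)) expect_true(all(cl$n_motifs >= 4L))
    }
})

test_that("planted clusters are recovered from the synthetic study", {
    fx <- getStudy()
    detected <- findMotifClusters(fx$groundTruth$motif_positions)
    planted <- fx$groundTruth$cluster_positions
    expect_gte(length(detected), length(planted))
    ov <- countOverlaps(planted, detected)
    expect_true(all(ov >= 1))
})

test_that("stratification splits peaks and motifs by overlap", {
    peaks <- gr1(c(1001, 5001), c(2000, 6000))
    hits <- gr1(1500, 1507)
    sp <- stratifyPeaksByMotif(peaks, hits)
    expect_equal(start(sp$with_motif), 1001)
    expect_equal(start(sp$without_motif), 5001)
    # empty hits: everything is motif-free
    sp0 <- stratifyPeaksByMotif(peaks, GRanges())
    expect_length(sp0$with_motif, 0)
    expect_length(sp0$without_motif, 2)

    sm <- stratifyMotifsByMark(hits, peaks)
    expect_length(sm$with_mark, 1)
    sm0 <- stratifyMotifsByMark(hits, GRanges())
    expect_length(sm0$with_mark, 0)
    expect_length(sm0$without_mark, 1)

    # random partition equals the all-pairs overlap oracle (motif start only)
    set.seed(41)
    ps <- sample(1:20000, 30)
    peaksR <- gr1(ps, ps + sample(200:900, 30, replace = TRUE))
    ms <- sample(1:21000, 80)
    hitsR <- gr1(ms, ms + 7L)
    spR <- stratifyPeaksByMotif(peaksR, hitsR)
    inPeak <- vapply(seq_along(peaksR), function(i)
        any(ms >= start(peaksR)[i] & ms <= end(peaksR)[i]), logical(1))
    expect_equal(sort(start(spR$with_motif)), sort(start(peaksR)[inPeak]))
    smR <- stratifyMotifsByMark(hitsR, peaksR)
    inMark <- vapply(ms, function(m)
        any(m >= start(peaksR) & m <= end(peaksR)), logical(1))
    expect_equal(sort(start(smR$with_mark)), sort(ms[inMark]))
})

test_that("windowTable counts motifs in 600 bp around bin centres", {
    mkTrack <- function(vals, label) new("ScaledTrack", binSize = 50L,
        values = S4Vectors::SimpleList(chr1 = vals),
        seqlengths = c(chr1 = length(vals) * 50L), label = label)
    h2 <- mkTrack(rep(2, 40), "h2aub")
    r6 <- mkTrack(rep(3, 40), "ref6")

    # no hits: all zero
    wt0 <- windowTable(h2, r6, GRanges())
    expect_true(all(wt0$n_motifs_600 == 0))
    expect_equal(nrow(wt0), 40)

    # hit at 0-based 750 counted for the bin [950,1000): centre 975,
    # window [675,1275)
    hit <- gr1(751, 758)
    wt1 <- windowTable(h2, r6, hit)
    binRow <- wt1[wt1$start == 951, ]
    expect_equal(binRow$n_motifs_600, 1L)
    # and not for the bin [1350,1400): centre 1375, window [1075,1675)
    expect_equal(wt1[wt1$start == 1351, ]$n_motifs_600, 0L)

    # conservation: an interior hit is counted in exactly 600/50 = 12 windows
    expect_equal(sum(wt1$n_motifs_600), 12L)
    # grid mismatch is an error
    bad <- mkTrack(rep(1, 30), "bad")
    expect_error(windowTable(h2, bad, GRanges()), "grid")
})

test_that("h2aubRef6Regression handles exact and degenerate strata", {
    rec <- data.frame(chrom = "chr1", start = 1, end = 50,
                      h2aub = c(1, 10, 100, 1000),
                      ref6 = c(1, 10, 100, 1000), n_motifs_600 = 0L)
    fit <- h2aubRef6Regression(rec, stratum = 0)
    expect_equal(unname(fit["slope"]), 1)
    expect_equal(unname(fit["r_squared"]), 1)

    recConst <- transform(rec, ref6 = 7)
    fitC <- h2aubRef6Regression(recConst, stratum = 0)
    expect_equal(unname(fitC["slope"]), 0)
    expect_equal(unname(fitC["r_squared"]), 0)

    expect_error(h2aubRef6Regression(transform(rec, h2aub = 5), stratum = 0),
                 "degenerate")

    # invariance to a common scale factor: slope unchanged, intercept shifts
    set.seed(51)
    rec2 <- data.frame(chrom = "chr1", start = 1, end = 50,
                       h2aub = rlnorm(200, 1, 0.5), n_motifs_600 = 0L)
    rec2$ref6 <- 10^(0.3 + 0.5 * log10(rec2$h2aub)) * rlnorm(200, 0, 0.05)
    f1 <- h2aubRef6Regression(rec2, stratum = 0)
    rec3 <- transform(rec2, h2aub = h2aub * 4, ref6 = ref6 * 4)
    f2 <- h2aubRef6Regression(rec3, stratum = 0)
    expect_equal(unname(f1["slope"]), unname(f2["slope"]), tolerance = 1e-10)
    expect_false(isTRUE(all.equal(f1[["intercept"]], f2[["intercept"]])))
})
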