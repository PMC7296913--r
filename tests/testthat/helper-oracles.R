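# Independent brute-force oracles and shared fixtures for the test suite.
# Oracles are deliberately naive (per-base masks, all-pairs scans, full
# enumeration) and never call the implementation paths they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(Biostrings)
})

gr1 <- function(starts, ends, chrom = "chr1", strand = "*") {
    GRanges(chrom, IRanges(starts, ends), strand = strand)
}

# minimal disjoint cover via a per-base boolean mask (single chromosome)
oracleMergeMask <- function(starts, ends) {
    mask <- logical(max(ends) + 1L)
    for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
    r <- rle(mask)
    stop_at <- cumsum(r$lengths)
    start_at <- c(1L, head(stop_at, -1) + 1L)
    keep <- r$values
    data.frame(start = start_at[keep], end = stop_at[keep])
}

# all-pairs interval overlap (1-based closed coordinates)
oracleOverlaps <- function(s1, e1, s2, e2) {
    outer(s1, e2, `<=`) & outer(e1, s2, `>=`)
}

# naive sliding-window scan for CTCTGYTY on both strands of a character
# sequence; returns 1-based starts and strands
oracleScanMotif <- function(seqchar) {
    chars <- strsplit(seqchar, "")[[1]]
    matchAt <- function(i, pat) {
        if (i + 7L > length(chars)) return(FALSE)
        win <- chars[i:(i + 7L)]
        all(mapply(function(c, p) {
            if (p == "Y") c %in% c("C", "T") else c == p
        }, win, strsplit(pat, "")[[1]]))
    }
    fwd <- which(vapply(seq_along(chars), matchAt, logical(1), pat = "CTCTGYTY"))
    # reverse-complement of CTCTGYTY is RARCAGAG (R = A or G)
    revMatchAt <- function(i) {
        if (i + 7L > length(chars)) return(FALSE)
        win <- chars[i:(i + 7L)]
        pat <- c("R", "A", "R", "C", "A", "G", "A", "G")
        all(mapply(function(c, p) {
            if (p == "R") c %in% c("A", "G") else c == p
        }, win, pat))
    }
    rev <- which(vapply(seq_along(chars), revMatchAt, logical(1)))
    data.frame(start = c(fwd, rev),
               strand = rep(c("+", "-"), c(length(fwd), length(rev))))
}

# brute-force motif clusters: every window of >= minMotifs consecutive hits
# whose first-to-last extent fits the window, merged on the number line
oracleClusters <- function(starts, window = 600L, minMotifs = 4L) {
    starts <- sort(starts)
    ends <- starts + 7L
    n <- length(starts)
    cand <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j >= i + minMotifs - 1L && ends[j] - starts[i] + 1L <= window)
            cand[[length(cand) + 1L]] <- c(starts[i], ends[j])
    }
    if (length(cand) == 0L) return(data.frame(start = integer(0), end = integer(0)))
    m <- do.call(rbind, cand)
    oracleMergeMask(m[, 1], m[, 2])
}

# exact two-sided Mann-Whitney p by enumerating all group labelings
oracleMannWhitneyP <- function(x, y) {
    vals <- c(x, y)
    n <- length(x)
    combos <- utils::combn(length(vals), n)
    uFor <- function(idx) {
        r <- rank(vals)
        sum(r[idx]) - n * (n + 1) / 2
    }
    uObs <- uFor(seq_len(n))
    us <- apply(combos, 2, uFor)
    pLow <- mean(us <= uObs)
    pHigh <- mean(us >= uObs)
    min(1, 2 * min(pLow, pHigh))
}

# exact upper-tail hypergeometric by direct summation of the pmf
oracleHyperP <- function(N, nA, nB, k) {
    js <- k:min(nA, nB)
    sum(choose(nA, js) * choose(N - nA, nB - js)) / choose(N, nB)
}

# shared study fixtures, generated once per test run
.fixtureCache <- new.env(parent = emptyenv())

smallConfig <- function(seed = 1L, ...) {
    args <- list(seed = seed, n_chroms = 1L, chrom_length = 200000L,
                 n_genes = 40L, n_targets = 6L, n_loss = 2L,
                 n_clusters = 2L)
    args <- utils::modifyList(args, list(...))
    do.call(simulationConfig, args)
}

getStudy <- function(key = "small", cfg = smallConfig()) {
    if (is.null(.fixtureCache[[key]]))
        .fixtureCache[[key]] <- generateStudy(cfg)
    .fixtureCache[[key]]
}
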