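#' @importFrom Biostrings DNAString DNAStringSet vmatchPattern reverseComplement
#' @importFrom stats lm
NULL

REF6_MOTIF <- "CTCTGYTY"

#' Scan a genome for the REF6-binding CTCTGYTY motif
#'
#' Finds all occurrences of the degenerate 8-mer CTCTGYTY (Y = C or T) on
#' both strands: forward matches are reported on \code{+}, positions whose
#' reverse complement matches on \code{-}. Ambiguity letters (N) in the
#' subject never match. The motif is non-palindromic so a position cannot be
#' double-counted, but forward and reverse hits at distinct coordinates are
#' both kept.
#'
#' @param genome a \link[Biostrings]{DNAStringSet} (one entry per
#'   chromosome, named) or a single \code{DNAString}/character string.
#' @return \code{GRanges} of 8-bp motif hits with strand, sorted.
#' @examples
#' scanMotifs(Biostrings::DNAStringSet(c(chr1 = "AACTCTGCTCAA")))
#' @export
scanMotifs <- function(genome) {
    if (is.character(genome)) genome <- DNAStringSet(genome)
    if (is(genome, "DNAString")) genome <- DNAStringSet(genome)
    if (is.null(names(genome)))
        names(genome) <- paste0("chr", seq_along(genome))
    fwd <- vmatchPattern(REF6_MOTIF, genome, fixed = "subject")
    rev <- vmatchPattern(as.character(reverseComplement(DNAString(REF6_MOTIF))),
                         genome, fixed = "subject")
    toGR <- function(byChrom, strand) {
        grs <- lapply(names(byChrom), function(chr) {
            ir <- byChrom[[chr]]
            if (length(ir) == 0L) return(NULL)
            GRanges(chr, ir, strand = rep(strand, length(ir)))
        })
        grs <- grs[!vapply(grs, is.null, logical(1))]
        if (length(grs) == 0L) return(GRanges())
        do.call(c, grs)
    }
    out <- suppressWarnings(c(toGR(fwd, "+"), toGR(rev, "-")))
    GenomeInfoDb::seqlengths(out) <- Biostrings::width(genome)[
        match(GenomeInfoDb::seqlevels(out), names(genome))]
    GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Detect clusters of CTCTGYTY motifs
#'
#' A cluster is a maximal run of at least \code{minMotifs} motif hits whose
#' first-to-last extent (start of the first motif to end of the last) fits
#' within \code{window} bp. Overlapping cluster intervals are merged and the
#' motif count recomputed on the merged interval.
#'
#' @param hits \code{GRanges} of motif hits (from [scanMotifs()]).
#' @param window window size in bp (default 600).
#' @param minMotifs minimum motifs per cluster (default 4).
#' @return \code{GRanges} of merged clusters with an \code{n_motifs}
#'   metadata column (always >= \code{minMotifs}).
#' @export
findMotifClusters <- function(hits, window = 600L, minMotifs = 4L) {
    hits <- GenomicRanges::sort(granges(hits), ignore.strand = TRUE)
    candidates <- list()
    for (chr in as.character(unique(seqnames(hits)))) {
        h <- hits[seqnames(hits) == chr]
        st <- start(h); en <- end(h)
        n <- length(h)
        if (n < minMotifs) next
        j <- 1L
        for (i in seq_len(n)) {
            if (j < i) j <- i
            # grow the run while the first-to-last extent fits the window
            while (j < n && en[j + 1L] - st[i] + 1L <= window) j <- j + 1L
            if (j - i + 1L >= minMotifs)
                candidates[[length(candidates) + 1L]] <-
                    GRanges(chr, IRanges(st[i], en[j]))
        }
    }
    if (length(candidates) == 0L)
        return(GRanges(n_motifs = integer(0)))
    clusters <- mergeIntervals(suppressWarnings(do.call(c, candidates)))
    starts <- GenomicRanges::resize(granges(hits), 1L, fix = "start", ignore.strand = TRUE)
    mcols(clusters)$n_motifs <-
        GenomicRanges::countOverlaps(clusters, starts, ignore.strand = TRUE)
    clusters
}

# leftmost coordinate of each motif as a 1-bp anchor (membership convention)
.motifAnchors <- function(hits) {
    GRanges(seqnames(hits), IRanges(start(hits), width = 1L))
}

#' Partition peaks by motif content
#'
#' Splits a peak set into peaks containing at least one CTCTGYTY motif
#' (judged by the motif's leftmost coordinate falling inside the peak) and
#' peaks containing none.
#'
#' @param peaks \code{GRanges}.
#' @param hits \code{GRanges} of motif hits.
#' @return list with elements \code{with_motif} and \code{without_motif}.
#' @export
stratifyPeaksByMotif <- function(peaks, hits) {
    has <- GenomicRanges::countOverlaps(peaks, .motifAnchors(hits),
                                        ignore.strand = TRUE) > 0L
    list(with_motif = peaks[has], without_motif = peaks[!has])
}

#' Partition motifs by mark overlap
#'
#' Splits motif hits into those whose leftmost coordinate falls inside a
#' significant mark peak (e.g. H2Aub1) and those outside all peaks.
#'
#' @param hits \code{GRanges} of motif hits.
#' @param markPeaks \code{GRanges} of mark peaks.
#' @return list with elements \code{with_mark} and \code{without_mark}.
#' @export
stratifyMotifsByMark <- function(hits, markPeaks) {
    inside <- GenomicRanges::countOverlaps(.motifAnchors(hits), markPeaks,
                                           ignore.strand = TRUE) > 0L
    list(with_mark = hits[inside], without_mark = hits[!inside])
}

#' Genome-wide window table of H2Aub1, REF6 and motif counts
#'
#' One record per 50-bp bin with the coverage-scaled H2Aub1 and REF6 values
#' and the number of motif hits whose start lies in the 600-bp window
#' centred on the bin centre.
#'
#' @param h2aub,ref6 [ScaledTrack-class] objects on identical bin grids.
#' @param hits \code{GRanges} of motif hits.
#' @param motifWindow motif-counting window in bp (default 600).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (1-based, closed), \code{h2aub}, \code{ref6}, \code{n_motifs_600}.
#' @export
windowTable <- function(h2aub, ref6, hits, motifWindow = 600L) {
    stopifnot(is(h2aub, "ScaledTrack"), is(ref6, "ScaledTrack"))
    if (binSize(h2aub) != binSize(ref6) ||
        !identical(seqLengths(h2aub), seqLengths(ref6)))
        stop("tracks are not on identical bin grids")
    bs <- binSize(h2aub)
    half <- motifWindow %/% 2L
    anchors <- .motifAnchors(hits)
    out <- lapply(names(seqLengths(h2aub)), function(chr) {
        v1 <- trackValues(h2aub)[[chr]]
        v2 <- trackValues(ref6)[[chr]]
        starts <- (seq_along(v1) - 1L) * bs + 1L
        ends <- pmin(starts + bs - 1L, seqLengths(h2aub)[[chr]])
        centre0 <- (starts - 1L) + bs %/% 2L # 0-based bin centre
        win <- GRanges(chr, IRanges(pmax(1L, centre0 - half + 1L),
                                    centre0 + half))
        nm <- GenomicRanges::countOverlaps(win, anchors, ignore.strand = TRUE)
        data.frame(chrom = chr, start = starts, end = ends,
                   h2aub = v1, ref6 = v2, n_motifs_600 = nm)
    })
    do.call(rbind, out)
}

#' Log-log regression of REF6 on H2Aub1 in 50-bp windows
#'
#' Ordinary least squares of \code{log10(ref6)} on \code{log10(h2aub)} over
#' the window records, optionally within one motif-count stratum. Strata are
#' the motif-count classes 0, 1, 2, 3, 4 and \code{"5+"} from the
#' \code{n_motifs_600} column. Scaled counts are strictly positive by
#' construction (+1 pseudocount), so the logs are always defined.
#'
#' @param records data.frame from [windowTable()].
#' @param stratum \code{NULL} (default: one fit per motif-count stratum
#'   present), a motif-count class (0:4 or \code{"5+"}), or \code{"all"}
#'   for a single pooled fit over every record.
#' @return If \code{stratum} is given, a named vector
#'   \code{(slope, intercept, r_squared, p_value, n)}; otherwise a
#'   data.frame with one row per stratum present (>= 3 records).
#' @export
h2aubRef6Regression <- function(records, stratum = NULL) {
    cls <- ifelse(records$n_motifs_600 >= 5L, "5+",
                  as.character(records$n_motifs_600))
    fitOne <- function(df) {
        if (nrow(df) < 3L)
            stop("need >= 3 records in the stratum")
        x <- log10(df$h2aub); y <- log10(df$ref6)
        if (stats::var(x) == 0)
            stop("degenerate H2Aub1 variance in the stratum")
        if (stats::var(y) == 0)
            return(c(slope = 0, intercept = mean(y), r_squared = 0,
                     p_value = 1, n = nrow(df)))
        fit <- lm(y ~ x)
        sm <- suppressWarnings(summary(fit)) # exact fits are legitimate here
        c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
          r_squared = sm$r.squared,
          p_value = if (nrow(sm$coefficients) > 1L) sm$coefficients[2, 4] else NA_real_,
          n = nrow(df))
    }
    if (!is.null(stratum)) {
        if (identical(as.character(stratum), "all")) return(fitOne(records))
        return(fitOne(records[cls == as.character(stratum), , drop = FALSE]))
    }
    strata <- intersect(c("0", "1", "2", "3", "4", "5+"), unique(cls))
    rows <- lapply(strata, function(s) {
        df <- records[cls == s, , drop = FALSE]
        if (nrow(df) < 3L || stats::var(log10(df$h2aub)) == 0) return(NULL)
        data.frame(stratum = s, t(fitOne(df)))
    })
    do.call(rbind, rows)
}
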