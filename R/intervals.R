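#' @importFrom GenomicRanges GRanges reduce findOverlaps strand start end width
#'   seqnames resize promoters trim
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom IRanges IRanges
NULL

.REGION_KINDS <- c("first_1kb", "first_20pct", "last_20pct", "upstream_2kb", "genic")

#' Derive an analysis region from a gene body
#'
#' Extracts, strand-aware, one of the standard analysis regions from each
#' gene body: the first 1 kb (\code{first_1kb}), the first or last 20\% of
#' the body (\code{first_20pct}, \code{last_20pct}; 20\% computed as
#' \code{floor(width * 0.2)} bp, at least 1 bp), the 2 kb upstream of the TSS
#' (\code{upstream_2kb}), or the genic region, defined as the gene body plus
#' 2 kb upstream (\code{genic}). "First" is measured from the transcription
#' start, so for a minus-strand gene it is the high-coordinate end. Regions
#' are truncated to the gene body (\code{first_1kb} of genes shorter than
#' 1 kb is the whole body) and clipped at chromosome bounds when seqlengths
#' are set.
#'
#' @param genes \code{GRanges} of gene bodies; strand \code{+}, \code{-} or
#'   \code{*} (treated as \code{+}).
#' @param kind one of \code{"first_1kb"}, \code{"first_20pct"},
#'   \code{"last_20pct"}, \code{"upstream_2kb"}, \code{"genic"}.
#' @return \code{GRanges} parallel to \code{genes}, with its metadata
#'   columns carried over.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 3000), strand = "+")
#' deriveRegion(g, "first_1kb")   # 1001-2000
#' deriveRegion(g, "last_20pct")  # 2601-3000
#' @export
deriveRegion <- function(genes, kind) {
    kind <- match.arg(kind, .REGION_KINDS)
    w <- width(genes)
    # out-of-bound intermediates are expected (upstream of a chromosome
    # start); they are clipped immediately below
    out <- suppressWarnings(switch(kind,
        first_1kb = resize(genes, pmin(w, 1000L), fix = "start"),
        first_20pct = resize(genes, pmax(1L, as.integer(floor(w * 0.2))), fix = "start"),
        last_20pct = resize(genes, pmax(1L, as.integer(floor(w * 0.2))), fix = "end"),
        upstream_2kb = promoters(genes, upstream = 2000L, downstream = 0L),
        genic = {
            up <- promoters(genes, upstream = 2000L, downstream = 0L)
            .pairUnion(genes, up) # contiguous: body plus its upstream flank
        }
    ))
    # clip at chromosome bounds where lengths are known; never below base 1
    out <- trim(out)
    if (any(start(out) < 1L))
        out <- GenomicRanges::restrict(out, start = 1L, keep.all.ranges = TRUE)
    out
}

.pairUnion <- function(a, b) {
    stopifnot(length(a) == length(b))
    res <- a
    start(res) <- pmin(start(a), start(b))
    end(res) <- pmax(end(a), end(b))
    res
}

#' Replicate-concordant peaks
#'
#' Keeps only peaks supported by both replicates: every pair of peaks (one
#' per replicate) overlapping by at least 1 bp is retained and the retained
#' peaks are merged, so transitively overlapping pair-unions collapse to a
#' single interval. Peaks with no cross-replicate overlap are dropped.
#'
#' @param peaksRep1,peaksRep2 \code{GRanges} of peak calls from the two
#'   replicates.
#' @return \code{GRanges} of merged concordant peaks, sorted; empty if either
#'   input is empty. Strand is ignored.
#' @export
intersectReplicates <- function(peaksRep1, peaksRep2) {
    # disjoint seqlevels between replicates are plain non-overlap, not an error
    hits <- suppressWarnings(
        findOverlaps(peaksRep1, peaksRep2, ignore.strand = TRUE))
    if (length(hits) == 0L)
        return(GRanges(seqlengths = .combinedSeqlengths(peaksRep1, peaksRep2)))
    kept <- suppressWarnings( # mixed seqlevels between replicates are fine
        c(granges(peaksRep1[unique(queryHits(hits))]),
          granges(peaksRep2[unique(subjectHits(hits))])))
    mergeIntervals(kept)
}

.combinedSeqlengths <- function(a, b) {
    sl <- c(seqlengths(a), seqlengths(b))
    sl[!duplicated(names(sl))]
}

#' Merge overlapping intervals
#'
#' Collapses a set of intervals into the minimal sorted set of disjoint
#' intervals covering the same bases (strand-blind).
#'
#' @param intervals \code{GRanges}.
#' @return \code{GRanges}, disjoint and sorted.
#' @export
mergeIntervals <- function(intervals) {
    out <- reduce(granges(intervals), ignore.strand = TRUE)
    GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Annotate peaks to genes via a derived region
#'
#' Associates every peak with every gene whose derived region (by default
#' the first 1 kb of the gene body) it overlaps by at least 1 bp. A peak may
#' annotate to several genes; genes without any overlapping peak are present
#' with zero-length entries. Callers are expected to pass a biotype-filtered
#' (protein-coding) gene set.
#'
#' @param peaks \code{GRanges} of peaks.
#' @param genes \code{GRanges} of gene bodies with a \code{gene_id} metadata
#'   column.
#' @param kind region kind passed to [deriveRegion()]; default
#'   \code{"first_1kb"}.
#' @return A named \code{GRangesList}-like ordinary list: gene_id ->
#'   \code{GRanges} of annotated peaks (possibly empty).
#' @export
annotatePeaksToGenes <- function(peaks, genes, kind = "first_1kb") {
    stopifnot(!is.null(genes$gene_id))
    regions <- deriveRegion(genes, kind)
    hits <- findOverlaps(regions, peaks, ignore.strand = TRUE)
    out <- vector("list", length(genes))
    names(out) <- genes$gene_id
    empty <- granges(peaks[0])
    for (i in seq_along(out)) out[[i]] <- empty
    if (length(hits)) {
        byGene <- split(subjectHits(hits), queryHits(hits))
        for (q in names(byGene))
            out[[as.integer(q)]] <- granges(peaks[byGene[[q]]])
    }
    out
}

#' Which genes have at least one peak in a derived region?
#'
#' Convenience predicate behind peak-based presence calls: \code{TRUE} for
#' genes whose derived region overlaps at least one peak by >= 1 bp.
#'
#' @inheritParams annotatePeaksToGenes
#' @return Named logical vector over \code{genes$gene_id}.
#' @export
genesWithPeak <- function(peaks, genes, kind = "first_1kb") {
    stopifnot(!is.null(genes$gene_id))
    regions <- deriveRegion(genes, kind)
    res <- GenomicRanges::countOverlaps(regions, peaks, ignore.strand = TRUE) > 0L
    names(res) <- genes$gene_id
    res
}
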