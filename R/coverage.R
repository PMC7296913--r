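#' @importFrom GenomicRanges tileGenome countOverlaps GRanges shift
#' @importFrom stats median approx setNames
NULL

#' Coverage-scale a raw fragment count
#'
#' The package's single scaling rule: \code{(raw + 1) / (coverage / 1e9)},
#' i.e. fragments-per-region plus a pseudocount of one, per gigabase of the
#' library's total base coverage. Scaling by sequenced bases rather than by
#' fragment number keeps libraries with different fragment lengths
#' comparable; the pseudocount keeps every scaled value positive so that
#' log-scale analyses are always defined.
#'
#' @param raw integer vector of raw fragment counts (>= 0).
#' @param totalBaseCoverage library total base coverage in bp (> 0).
#' @return numeric vector of scaled counts.
#' @examples
#' scaleCounts(4, 2e9) # 2.5
#' @export
scaleCounts <- function(raw, totalBaseCoverage) {
    if (length(totalBaseCoverage) != 1L || is.na(totalBaseCoverage) ||
        totalBaseCoverage <= 0)
        stop("'totalBaseCoverage' must be a single positive number")
    if (any(raw < 0)) stop("'raw' counts must be non-negative")
    (raw + 1) / (totalBaseCoverage / 1e9)
}

#' Genome-wide binned, coverage-scaled track for one library
#'
#' Tiles every chromosome with fixed-width bins anchored at the first base
#' and counts, per bin, the fragments overlapping it by at least 1 bp (a
#' fragment is counted once in every bin it overlaps). Raw bin counts are
#' then scaled with [scaleCounts()].
#'
#' @param lib a [FragmentLibrary-class].
#' @param seqlengths named integer vector of chromosome lengths; defaults to
#'   the seqlengths of the library's fragments (which must then be set).
#' @param binSize bin width in bp, default 50.
#' @return A [ScaledTrack-class].
#' @export
binTrack <- function(lib, seqlengths = NULL, binSize = 50L) {
    stopifnot(is(lib, "FragmentLibrary"))
    binSize <- as.integer(binSize)
    if (binSize < 1L) stop("'binSize' must be >= 1")
    if (is.null(seqlengths)) {
        seqlengths <- seqlengths(fragments(lib))
        if (any(is.na(seqlengths)))
            stop("fragment GRanges carries no seqlengths; pass 'seqlengths'")
    }
    seqlengths <- seqlengths[order(names(seqlengths))]
    bins <- tileGenome(seqlengths, tilewidth = binSize,
                       cut.last.tile.in.chrom = TRUE)
    raw <- countOverlaps(bins, fragments(lib), ignore.strand = TRUE)
    scaled <- scaleCounts(raw, totalBaseCoverage(lib))
    values <- split(scaled, factor(as.character(seqnames(bins)),
                                   levels = names(seqlengths)))
    new("ScaledTrack", binSize = binSize,
        values = SimpleList(lapply(values, as.numeric)),
        seqlengths = vapply(seqlengths, as.integer, integer(1)),
        label = libraryId(lib))
}

#' Average replicate tracks
#'
#' Element-wise arithmetic mean of scaled tracks on identical bin grids.
#' Scaling happens per library first; replicates are combined only
#' afterwards.
#'
#' @param tracks list of [ScaledTrack-class] objects on identical grids.
#' @param label label for the averaged track.
#' @return A [ScaledTrack-class].
#' @export
averageReplicates <- function(tracks, label = "averaged") {
    stopifnot(length(tracks) >= 1L, all(vapply(tracks, is, logical(1), "ScaledTrack")))
    ref <- tracks[[1]]
    for (t in tracks[-1]) {
        if (binSize(t) != binSize(ref) ||
            !identical(seqLengths(t), seqLengths(ref)))
            stop("tracks are not on identical bin grids")
    }
    vals <- lapply(names(trackValues(ref)), function(chr) {
        m <- vapply(tracks, function(t) trackValues(t)[[chr]],
                    numeric(length(trackValues(ref)[[chr]])))
        if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
        rowMeans(m)
    })
    names(vals) <- names(trackValues(ref))
    new("ScaledTrack", binSize = binSize(ref), values = SimpleList(vals),
        seqlengths = seqLengths(ref), label = label)
}

#' Coverage-scaled fragment counts over gene regions
#'
#' Counts, per gene, the fragments overlapping a derived gene region (first
#' 1 kb, first 20\%, last 20\%, ...) by at least 1 bp, and applies the same
#' coverage scaling as the binned tracks.
#'
#' @param lib a [FragmentLibrary-class].
#' @param genes \code{GRanges} with a \code{gene_id} column.
#' @param kind region kind, see [deriveRegion()]; default \code{"first_1kb"}.
#' @return named numeric vector of scaled counts, one per gene.
#' @export
regionCounts <- function(lib, genes, kind = "first_1kb") {
    stopifnot(is(lib, "FragmentLibrary"), !is.null(genes$gene_id))
    regions <- deriveRegion(genes, kind)
    raw <- countOverlaps(regions, fragments(lib), ignore.strand = TRUE)
    out <- scaleCounts(raw, totalBaseCoverage(lib))
    names(out) <- genes$gene_id
    out
}

#' Average replicate region counts
#'
#' @param countsList list of named numeric vectors from [regionCounts()],
#'   one per replicate, over the same gene universe.
#' @return named numeric vector, element-wise mean.
#' @export
averageRegionCounts <- function(countsList) {
    stopifnot(length(countsList) >= 1L)
    nm <- names(countsList[[1]])
    for (x in countsList[-1])
        if (!identical(names(x), nm)) stop("gene universes differ between replicates")
    m <- vapply(countsList, identity, numeric(length(nm)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(nm))
    out <- rowMeans(m)
    names(out) <- nm
    out
}

#' Mutant-minus-wild-type differential region counts
#'
#' Per-gene difference of replicate-averaged, coverage-scaled region counts:
#' positive values are gains in the mutant.
#'
#' @param mutant,wt named numeric vectors over the same gene universe.
#' @return named numeric vector \code{mutant - wt}.
#' @export
differentialCounts <- function(mutant, wt) {
    missing <- setdiff(names(mutant), names(wt))
    if (length(missing) || length(mutant) != length(wt))
        stop("gene universes differ; first missing gene: ",
             if (length(missing)) missing[1] else setdiff(names(wt), names(mutant))[1])
    mutant - wt[names(mutant)]
}

# value of the track at arbitrary genomic positions (1-based); NA outside
.trackAt <- function(track, chrom, pos) {
    vals <- trackValues(track)[[chrom]]
    if (is.null(vals)) return(rep(NA_real_, length(pos)))
    idx <- (pos - 1L) %/% binSize(track) + 1L
    out <- rep(NA_real_, length(pos))
    ok <- pos >= 1L & idx <= length(vals)
    out[ok] <- vals[idx[ok]]
    out
}

#' Metagene profile of a scaled track
#'
#' Median profile of a track across a set of genes: each gene body is
#' rescaled to \code{bodyBins} relative positions (linear interpolation of
#' the body's native 50-bp bin values), while the upstream and downstream
#' flanks are kept at native bin resolution. Profiles are read 5' to 3', so
#' minus-strand genes are reversed. The profile value at each position is
#' the median across genes (positions outside a chromosome are ignored).
#'
#' @param track a [ScaledTrack-class].
#' @param genes \code{GRanges} of gene bodies.
#' @param flank flank width in bp on each side (default 2000).
#' @param bodyBins number of relative body bins (default 100).
#' @return numeric vector of length \code{2 * flank / binSize + bodyBins};
#'   names give the position class (\code{up*}, \code{body*}, \code{down*}).
#' @export
metageneProfile <- function(track, genes, flank = 2000L, bodyBins = 100L) {
    stopifnot(is(track, "ScaledTrack"), length(genes) >= 1L,
              flank >= 0L, bodyBins >= 1L)
    bs <- binSize(track)
    if (flank %% bs != 0L) stop("'flank' must be a multiple of the track bin size")
    nFlank <- flank %/% bs
    rows <- vapply(seq_along(genes), function(i) {
        chrom <- as.character(seqnames(genes)[i])
        s <- start(genes)[i]; e <- end(genes)[i]
        minus <- as.character(strand(genes)[i]) == "-"
        # native bin values across the body
        bodyPos <- seq(s, e, by = bs)
        body <- .trackAt(track, chrom, bodyPos)
        if (length(body) == 1L) body <- rep(body, 2L)
        bodyR <- stats::approx(seq_along(body), body, n = bodyBins)$y
        upPos <- if (nFlank) s - bs * (nFlank:1) else integer(0)
        dnPos <- if (nFlank) e + bs * (1:nFlank) else integer(0)
        up <- .trackAt(track, chrom, upPos)
        dn <- .trackAt(track, chrom, dnPos)
        prof <- c(up, bodyR, dn)
        if (minus) prof <- rev(prof)
        prof
    }, numeric(2L * nFlank + bodyBins))
    if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
    prof <- apply(rows, 1L, median, na.rm = TRUE)
    names(prof) <- c(if (nFlank) paste0("up", nFlank:1),
                     paste0("body", seq_len(bodyBins)),
                     if (nFlank) paste0("down", seq_len(nFlank)))
    prof
}

#' Median track profile around summits
#'
#' Median, across a set of summit positions, of the track value at each
#' signed offset in \code{[-halfWindow, +halfWindow]} (step = bin size).
#' Summit-centred profiles are how REF6 enrichment at narrow H2Aub1 peak
#' summits is displayed.
#'
#' @param track a [ScaledTrack-class].
#' @param summits \code{GRanges} of single-base summit positions.
#' @param halfWindow half-window in bp; must be a multiple of the bin size.
#' @return named numeric vector (names are signed offsets); empty with a
#'   warning if \code{summits} is empty.
#' @export
summitProfile <- function(track, summits, halfWindow = 1000L) {
    stopifnot(is(track, "ScaledTrack"))
    bs <- binSize(track)
    if (halfWindow %% bs != 0L) stop("'halfWindow' must be a multiple of the bin size")
    if (length(summits) == 0L) {
        warning("empty summit list; returning empty profile")
        return(setNames(numeric(0), character(0)))
    }
    offsets <- seq(-halfWindow, halfWindow, by = bs)
    rows <- vapply(seq_along(summits), function(i) {
        chrom <- as.character(seqnames(summits)[i])
        .trackAt(track, chrom, start(summits)[i] + offsets)
    }, numeric(length(offsets)))
    if (is.null(dim(rows))) rows <- matrix(rows, nrow = length(offsets))
    prof <- apply(rows, 1L, median, na.rm = TRUE)
    names(prof) <- offsets
    prof
}
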