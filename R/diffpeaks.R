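#' @importFrom stats pbinom mad coef lm.fit
NULL

#' M-A transform of paired fragment counts
#'
#' \code{M = log2((a + 0.5) / (b + 0.5))} and
#' \code{A = 0.5 * log2((a + 0.5) * (b + 0.5))}. The 0.5 pseudocount guards
#' zero counts, standard M-A practice for ChIP-seq peak comparison.
#'
#' @param countA,countB non-negative fragment counts (vectorized).
#' @return data.frame with columns \code{M} and \code{A}.
#' @examples
#' computeMA(15, 3) # M = log2(15.5/3.5)
#' @export
computeMA <- function(countA, countB) {
    if (any(countA < 0) || any(countB < 0)) stop("counts must be non-negative")
    data.frame(M = log2((countA + 0.5) / (countB + 0.5)),
               A = 0.5 * log2((countA + 0.5) * (countB + 0.5)))
}

# single point per fragment: the 5' end shifted into the fragment by
# 'shift' bp (default half the fragment's own length, i.e. its midpoint)
.fragmentPoints <- function(fragGR, shiftBy = NULL) {
    if (is.null(shiftBy)) shiftBy <- width(fragGR) %/% 2L
    minus <- as.character(strand(fragGR)) == "-"
    pos <- ifelse(minus, end(fragGR) - shiftBy, start(fragGR) + shiftBy)
    GRanges(seqnames(fragGR), IRanges(pos, width = 1L))
}

#' Build a peak catalogue with windowed counts from two samples
#'
#' Merges the peak calls of samples A and B into a single catalogue and
#' counts, for each merged peak, the fragments of each sample falling in a
#' fixed-size window centred on the peak midpoint. Each fragment is
#' represented by a single position: its 5' end shifted by half the fragment
#' length (configurable via \code{shiftBy}). A catalogue peak has origin
#' \code{common} if it overlaps peaks from both samples, else
#' \code{unique_a} / \code{unique_b}.
#'
#' @param peaksA,peaksB \code{GRanges} peak calls of the two samples.
#' @param libA,libB [FragmentLibrary-class] objects for the two samples.
#' @param windowSize window in bp centred on the peak midpoint (default 1000).
#' @param shiftBy fragment 5'-end shift in bp, or \code{NULL} (default) for
#'   half of each fragment's own length.
#' @return \code{GRanges} of merged catalogue peaks with metadata columns
#'   \code{count_a}, \code{count_b}, \code{origin}, \code{M}, \code{A}.
#' @export
peakCatalogue <- function(peaksA, peaksB, libA, libB,
                          windowSize = 1000L, shiftBy = NULL) {
    catalogue <- mergeIntervals(c(granges(peaksA), granges(peaksB)))
    if (length(catalogue) == 0L) return(catalogue)
    fromA <- GenomicRanges::countOverlaps(catalogue, peaksA, ignore.strand = TRUE) > 0L
    fromB <- GenomicRanges::countOverlaps(catalogue, peaksB, ignore.strand = TRUE) > 0L
    origin <- ifelse(fromA & fromB, "common", ifelse(fromA, "unique_a", "unique_b"))
    mid <- (start(catalogue) + end(catalogue)) %/% 2L
    win <- GRanges(seqnames(catalogue),
                   IRanges(pmax(1L, mid - windowSize %/% 2L),
                           width = windowSize))
    ptsA <- .fragmentPoints(fragments(libA), shiftBy)
    ptsB <- .fragmentPoints(fragments(libB), shiftBy)
    countA <- GenomicRanges::countOverlaps(win, ptsA, ignore.strand = TRUE)
    countB <- GenomicRanges::countOverlaps(win, ptsB, ignore.strand = TRUE)
    ma <- computeMA(countA, countB)
    mcols(catalogue) <- DataFrame(count_a = countA, count_b = countB,
                                  origin = origin, M = ma$M, A = ma$A)
    catalogue
}

# Huber-weighted iteratively reweighted least squares of M on A.
# k = 1.345 on the MAD scale; at most maxit iterations, coefficient
# tolerance tol. An exact fit (zero residual scale) short-circuits.
.huberFit <- function(A, M, maxit = 50L, tol = 1e-8, k = 1.345) {
    X <- cbind(1, A)
    beta <- lm.fit(X, M)$coefficients
    if (anyNA(beta)) stop("degenerate design: need >= 2 distinct A values")
    for (it in seq_len(maxit)) {
        r <- M - X %*% beta
        s <- mad(r, center = 0)
        if (s < 1e-12) break
        w <- pmin(1, k / (abs(r) / s))
        fit <- lm.fit(X * sqrt(as.vector(w)), M * sqrt(as.vector(w)))
        newBeta <- fit$coefficients
        if (max(abs(newBeta - beta)) < tol) {
            beta <- newBeta
            break
        }
        beta <- newBeta
    }
    c(intercept = unname(beta[1]), slope = unname(beta[2]))
}

#' Fit the M-A normalization line on common peaks
#'
#' Robust linear fit of M on A over the peaks common to both samples
#' (Huber-weighted iteratively reweighted least squares, at most 50
#' iterations, tolerance 1e-8), optionally stabilized by a bootstrap: the
#' fit is recomputed on \code{nSimulations} resamples of the common peaks
#' and the median intercept/slope is returned. The fitted line captures the
#' global between-sample ratio under the assumption that common peaks are,
#' on average, equally enriched in both samples.
#'
#' @param catalogue output of [peakCatalogue()] (or any GRanges/data.frame
#'   with columns \code{M}, \code{A}, \code{origin}).
#' @param nSimulations bootstrap resamples (default 100); 0 disables the
#'   bootstrap. Uses the current RNG state.
#' @return named numeric vector \code{c(intercept, slope)}.
#' @export
fitNormalization <- function(catalogue, nSimulations = 100L) {
    df <- as.data.frame(mcols(catalogue))
    common <- df[df$origin == "common", , drop = FALSE]
    if (nrow(common) < 2L || length(unique(common$A)) < 2L)
        stop("normalization requires >= 2 common peaks with distinct A")
    base <- .huberFit(common$A, common$M)
    if (nSimulations > 0L) {
        boots <- vapply(seq_len(nSimulations), function(i) {
            idx <- sample.int(nrow(common), replace = TRUE)
            if (length(unique(common$A[idx])) < 2L) return(c(NA_real_, NA_real_))
            tryCatch(.huberFit(common$A[idx], common$M[idx]),
                     error = function(e) c(NA_real_, NA_real_))
        }, numeric(2))
        est <- apply(boots, 1L, median, na.rm = TRUE)
        if (!anyNA(est))
            base <- c(intercept = unname(est[1]), slope = unname(est[2]))
    }
    base
}

#' Rescale M by the normalization fit and test each peak
#'
#' Computes \code{M_norm = M - (intercept + slope * A)}, back-solves the
#' rescaled counts \code{a' = 2^(A + M_norm/2) - 0.5},
#' \code{b' = 2^(A - M_norm/2) - 0.5}, and assigns each peak a two-sided
#' exact binomial p-value for a split at least as extreme as
#' \code{(round(a'), round(b'))} under equal probability. Peaks are
#' significant when \code{p < pCutoff} and \code{|M_norm| > mCutoff};
#' direction is \code{up} (A over B) for positive \code{M_norm}.
#'
#' @param catalogue output of [peakCatalogue()].
#' @param fit named vector from [fitNormalization()] (or
#'   \code{c(intercept = 0, slope = 0)} for the identity).
#' @param pCutoff significance cutoff on the binomial p (default 0.05).
#' @param mCutoff cutoff on \code{|M_norm|} (default 0).
#' @return the catalogue \code{GRanges} with added metadata columns
#'   \code{M_norm}, \code{p_value}, \code{direction}, \code{significant}.
#' @export
normalizeAndTest <- function(catalogue, fit, pCutoff = 0.05, mCutoff = 0) {
    df <- mcols(catalogue)
    mNorm <- df$M - (fit[["intercept"]] + fit[["slope"]] * df$A)
    aPrime <- pmax(0, 2^(df$A + mNorm / 2) - 0.5)
    bPrime <- pmax(0, 2^(df$A - mNorm / 2) - 0.5)
    ka <- round(aPrime); kb <- round(bPrime)
    n <- ka + kb
    kmax <- pmax(ka, kb)
    p <- ifelse(n == 0, 1,
                pmin(1, 2 * pbinom(kmax - 1, n, 0.5, lower.tail = FALSE)))
    mcols(catalogue)$M_norm <- mNorm
    mcols(catalogue)$p_value <- p
    mcols(catalogue)$direction <- ifelse(mNorm > 0, "up", "down")
    mcols(catalogue)$significant <- p < pCutoff & abs(mNorm) > mCutoff
    catalogue
}

#' Differential peaks for one replicate comparison
#'
#' Convenience wrapper running [peakCatalogue()], [fitNormalization()] and
#' [normalizeAndTest()] for one mutant-vs-wild-type replicate pair and
#' returning only the significant differential peaks.
#'
#' @inheritParams peakCatalogue
#' @inheritParams normalizeAndTest
#' @param nSimulations passed to [fitNormalization()].
#' @return \code{GRanges} of significant differential peaks with
#'   \code{M_norm}, \code{p_value}, \code{direction}.
#' @export
differentialPeaks <- function(peaksA, peaksB, libA, libB,
                              windowSize = 1000L, shiftBy = NULL,
                              nSimulations = 100L,
                              pCutoff = 0.05, mCutoff = 0) {
    catalogue <- peakCatalogue(peaksA, peaksB, libA, libB,
                               windowSize = windowSize, shiftBy = shiftBy)
    if (length(catalogue) == 0L) return(catalogue)
    fit <- fitNormalization(catalogue, nSimulations = nSimulations)
    tested <- normalizeAndTest(catalogue, fit, pCutoff = pCutoff, mCutoff = mCutoff)
    tested[mcols(tested)$significant]
}

#' Replicate-concordant differential peaks
#'
#' Keeps only differential peaks detected in both replicate comparisons with
#' the same direction of change (overlap by at least 1 bp); concordant peaks
#' are merged per direction.
#'
#' @param rep1,rep2 \code{GRanges} of significant differential peaks (with a
#'   \code{direction} metadata column) from the two replicate comparisons.
#' @return \code{GRanges} of merged concordant peaks with a
#'   \code{direction} column.
#' @export
concordantDifferentialPeaks <- function(rep1, rep2) {
    pieces <- lapply(c("up", "down"), function(d) {
        a <- rep1[mcols(rep1)$direction == d]
        b <- rep2[mcols(rep2)$direction == d]
        merged <- intersectReplicates(a, b)
        if (length(merged)) mcols(merged)$direction <- d
        merged
    })
    out <- suppressWarnings(c(pieces[[1]], pieces[[2]]))
    GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Define deubiquitinase (UBP12/13) target genes
#'
#' Targets are the protein-coding genes whose first 1 kb overlaps at least
#' one replicate-concordant peak of H2Aub1 increase, minus any gene whose
#' first 1 kb also overlaps a peak of H2Aub1 decrease (gain that is
#' unambiguous).
#'
#' @param upPeaks,downPeaks \code{GRanges} of concordant up / down peaks.
#' @param genes \code{GRanges} of (protein-coding) gene bodies with
#'   \code{gene_id}.
#' @return character vector of target gene ids, sorted.
#' @export
defineUbpTargets <- function(upPeaks, downPeaks, genes) {
    up <- genesWithPeak(upPeaks, genes)
    down <- genesWithPeak(downPeaks, genes)
    sort(names(up)[up & !down])
}
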