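#' Per-gene mark presence calls
#'
#' A gene carries a mark iff at least one replicate-concordant ("real") peak
#' overlaps the first 1 kb of its gene body by at least 1 bp. Presence is
#' binary: enrichment magnitude never enters the call.
#'
#' @param realPeaks \code{GRanges} of replicate-concordant peaks for one
#'   mark.
#' @param genes \code{GRanges} of gene bodies with \code{gene_id}.
#' @param kind region kind (default \code{"first_1kb"}).
#' @return named logical vector over the gene universe.
#' @export
callMarkPresence <- function(realPeaks, genes, kind = "first_1kb") {
    genesWithPeak(realPeaks, genes, kind = kind)
}

#' Four-way H2Aub1 / H3K27me3 gene categorization
#'
#' Partitions the gene universe into the four mutually exclusive,
#' collectively exhaustive categories \code{not_marked}, \code{h2aub_only},
#' \code{both} and \code{k27_only} from the two presence maps.
#'
#' @param h2aub,k27 named logical vectors over the same gene universe.
#' @param h2az,ref6 optional named logical vectors (same universe).
#' @param isTarget optional named logical vector flagging target genes.
#' @return A [GeneMarkTable-class].
#' @export
categorizeMarks <- function(h2aub, k27, h2az = NULL, ref6 = NULL,
                            isTarget = NULL) {
    if (!setequal(names(h2aub), names(k27)) || length(h2aub) != length(k27))
        stop("h2aub and k27 presence maps cover different gene universes")
    k27 <- k27[names(h2aub)]
    tab <- DataFrame(gene_id = names(h2aub),
                     h2aub = unname(h2aub), k27 = unname(k27),
                     category = markCategory(unname(h2aub), unname(k27)))
    for (extra in c("h2az", "ref6", "isTarget")) {
        v <- get(extra)
        if (!is.null(v)) {
            if (!setequal(names(v), tab$gene_id))
                stop("'", extra, "' covers a different gene universe")
            col <- if (extra == "isTarget") "is_target" else extra
            tab[[col]] <- unname(v[tab$gene_id])
        }
    }
    new("GeneMarkTable", table = tab)
}

#' Per-category gene counts and fractions
#'
#' @param x a [GeneMarkTable-class].
#' @return data.frame with columns \code{category}, \code{n},
#'   \code{fraction}; the four categories always appear and the counts sum
#'   to the universe size.
#' @export
categoryCounts <- function(x) {
    stopifnot(is(x, "GeneMarkTable"))
    lev <- c("not_marked", "h2aub_only", "both", "k27_only")
    n <- table(factor(as.character(markTable(x)$category), levels = lev))
    data.frame(category = lev, n = as.integer(n),
               fraction = as.integer(n) / nrow(markTable(x)))
}

#' PRC1-dependency classification of H3K27me3-marked genes
#'
#' H3K27me3-marked genes whose first 1 kb overlaps a replicate-concordant
#' peak of decreased H3K27me3 in the PRC1 mutant are PRC1-dependent
#' (\code{prc1_dep}); all other H3K27me3-marked genes are PRC1-independent
#' (\code{prc1_indep}); genes without H3K27me3 are \code{non_k27} regardless
#' of peak overlap.
#'
#' @param k27 named logical presence vector.
#' @param decreasedK27Peaks \code{GRanges} of concordant down-direction
#'   differential H3K27me3 peaks in the PRC1 mutant.
#' @param genes \code{GRanges} of gene bodies with \code{gene_id} covering
#'   the same universe.
#' @return named character vector: \code{prc1_dep}, \code{prc1_indep} or
#'   \code{non_k27}.
#' @export
classifyPrc1Dependency <- function(k27, decreasedK27Peaks, genes) {
    stopifnot(setequal(names(k27), genes$gene_id))
    dec <- genesWithPeak(decreasedK27Peaks, genes)[names(k27)]
    out <- ifelse(!k27, "non_k27", ifelse(dec, "prc1_dep", "prc1_indep"))
    names(out) <- names(k27)
    out
}

#' Fraction of a gene set with a given boolean property
#'
#' E.g. the fraction of target genes marked with H3K27me3 (the "74\% of
#' targets are PRC2 targets" style of summary).
#'
#' @param geneSet character vector of gene ids (non-empty, subset of the
#'   table's universe).
#' @param x a [GeneMarkTable-class].
#' @param field name of a logical column of the table (\code{"h2aub"},
#'   \code{"k27"}, ...).
#' @return proportion in \code{[0, 1]}.
#' @export
categoryFraction <- function(geneSet, x, field) {
    stopifnot(is(x, "GeneMarkTable"))
    tab <- markTable(x)
    if (length(geneSet) == 0L) stop("empty gene set: fraction undefined")
    if (!all(geneSet %in% tab$gene_id))
        stop("gene set contains ids outside the table's universe")
    if (!field %in% colnames(tab) || !is.logical(tab[[field]]))
        stop("'", field, "' is not a logical column of the table")
    vals <- tab[[field]][match(geneSet, tab$gene_id)]
    sum(vals) / length(geneSet)
}
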