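#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
NULL

#' FragmentLibrary: one ChIP replicate's fragment intervals
#'
#' A \code{FragmentLibrary} holds the sequenced-fragment intervals of one
#' ChIP library (one antibody, one genotype, one replicate) as a
#' \link[GenomicRanges]{GRanges}, together with the library's total base
#' coverage (the summed fragment lengths in bp). The total base coverage is
#' the denominator of all coverage-scaled fragment counts: scaling by bases
#' rather than by fragment number keeps libraries with different fragment
#' lengths comparable.
#'
#' @slot libraryId character(1), unique library label.
#' @slot antibody character(1), e.g. \code{"H2Aub1"}, \code{"H3K27me3"},
#'   \code{"REF6"}, \code{"H3"}.
#' @slot genotype character(1), \code{"wt"} or \code{"mutant"}.
#' @slot replicate integer(1), replicate number within antibody x genotype.
#' @slot fragments GRanges of fragment intervals.
#' @slot totalBaseCoverage numeric(1), sum of fragment widths in bp; must
#'   equal the recomputed sum and be positive.
#'
#' @seealso [FragmentLibrary()] for the user-facing constructor,
#'   [binTrack()] and [regionCounts()] for quantification.
#' @export
setClass("FragmentLibrary",
    slots = c(
        libraryId = "character",
        antibody = "character",
        genotype = "character",
        replicate = "integer",
        fragments = "GRanges",
        totalBaseCoverage = "numeric"
    )
)

setValidity("FragmentLibrary", function(object) {
    msg <- NULL
    if (length(object@libraryId) != 1L || is.na(object@libraryId))
        msg <- c(msg, "'libraryId' must be a single non-NA string")
    if (!object@genotype %in% c("wt", "mutant"))
        msg <- c(msg, "'genotype' must be 'wt' or 'mutant'")
    recomputed <- sum(as.numeric(GenomicRanges::width(object@fragments)))
    if (!isTRUE(all.equal(recomputed, object@totalBaseCoverage)))
        msg <- c(msg, "'totalBaseCoverage' does not equal the summed fragment widths")
    if (object@totalBaseCoverage <= 0)
        msg <- c(msg, "'totalBaseCoverage' must be positive (empty libraries are not valid)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a FragmentLibrary
#'
#' @param fragments \code{GRanges} of fragment intervals.
#' @param antibody character(1) antibody name.
#' @param genotype character(1), \code{"wt"} or \code{"mutant"}.
#' @param replicate integer(1) replicate number.
#' @param libraryId character(1); default is
#'   \code{"<antibody>_<genotype>_rep<replicate>"}.
#'
#' @return A [FragmentLibrary-class] object. Total base coverage is computed
#'   from the fragments.
#' @examples
#' fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), width = 200))
#' FragmentLibrary(fr, "H2Aub1", "wt", 1L)
#' @export
FragmentLibrary <- function(fragments, antibody, genotype, replicate = 1L,
                            libraryId = NULL) {
    replicate <- as.integer(replicate)
    if (is.null(libraryId))
        libraryId <- sprintf("%s_%s_rep%d", antibody, genotype, replicate)
    new("FragmentLibrary",
        libraryId = libraryId, antibody = antibody, genotype = genotype,
        replicate = replicate, fragments = fragments,
        totalBaseCoverage = sum(as.numeric(GenomicRanges::width(fragments))))
}

#' ScaledTrack: genome-wide coverage-scaled fragment counts in fixed bins
#'
#' Per-chromosome numeric vectors of coverage-scaled fragment counts
#' ((fragments overlapping the bin + 1) per gigabase of library coverage) on
#' a bin grid anchored at the first base of each chromosome. Tracks from
#' replicate libraries share the grid and can be averaged element-wise.
#'
#' @slot binSize integer(1), bin width in bp (50 by default throughout).
#' @slot values SimpleList of per-chromosome numeric vectors; vector i has
#'   \code{ceiling(seqlengths[i] / binSize)} elements.
#' @slot seqlengths named integer vector of chromosome lengths.
#' @slot label character(1) free-text label (library id or condition).
#' @export
setClass("ScaledTrack",
    slots = c(
        binSize = "integer",
        values = "SimpleList",
        seqlengths = "integer",
        label = "character"
    )
)

setValidity("ScaledTrack", function(object) {
    msg <- NULL
    if (length(object@binSize) != 1L || object@binSize < 1L)
        msg <- c(msg, "'binSize' must be a single integer >= 1")
    if (!identical(names(object@values), names(object@seqlengths)))
        msg <- c(msg, "names of 'values' and 'seqlengths' must match")
    expected <- ceiling(object@seqlengths / object@binSize)
    got <- vapply(object@values, length, integer(1))
    if (length(got) && any(got != expected))
        msg <- c(msg, "per-chromosome value vectors do not tile the chromosomes")
    if (is.null(msg)) TRUE else msg
})

#' GeneMarkTable: per-gene mark presence, category and PRC1 dependency
#'
#' One row per gene with boolean presence calls for H2Aub1 and H3K27me3
#' (optionally H2A.Z and REF6), the four-way category label, the
#' PRC1-dependency class, and target status. Categories are mutually
#' exclusive and exhaustive: \code{not_marked}, \code{h2aub_only},
#' \code{both}, \code{k27_only}.
#'
#' @slot table \link[S4Vectors]{DataFrame} with columns \code{gene_id},
#'   \code{h2aub}, \code{k27}, \code{category}, and optionally
#'   \code{h2az}, \code{ref6}, \code{prc1_class}, \code{is_target}.
#' @export
setClass("GeneMarkTable", slots = c(table = "DataFrame"))

setValidity("GeneMarkTable", function(object) {
    tab <- object@table
    msg <- NULL
    req <- c("gene_id", "h2aub", "k27", "category")
    if (!all(req %in% colnames(tab)))
        return(paste("missing columns:", paste(setdiff(req, colnames(tab)), collapse = ", ")))
    if (anyDuplicated(tab$gene_id))
        msg <- c(msg, "'gene_id' must be unique")
    expected <- markCategory(tab$h2aub, tab$k27)
    if (!identical(as.character(tab$category), expected))
        msg <- c(msg, "'category' is inconsistent with the h2aub/k27 booleans")
    if ("prc1_class" %in% colnames(tab)) {
        pc <- as.character(tab$prc1_class)
        if (any((pc == "non_k27") != !tab$k27))
            msg <- c(msg, "prc1_class 'non_k27' must coincide with k27 == FALSE")
    }
    if (is.null(msg)) TRUE else msg
})

# four-way label from the two presence booleans
markCategory <- function(h2aub, k27) {
    ifelse(h2aub & k27, "both",
        ifelse(h2aub, "h2aub_only",
            ifelse(k27, "k27_only", "not_marked")))
}

#' @describeIn FragmentLibrary-class display a short summary
#' @param object a \code{FragmentLibrary}
#' @export
setMethod("show", "FragmentLibrary", function(object) {
    cat("FragmentLibrary:", object@libraryId, "\n",
        " antibody:", object@antibody,
        " genotype:", object@genotype,
        " replicate:", object@replicate, "\n",
        " fragments:", length(object@fragments),
        sprintf(" totalBaseCoverage: %.3g bp", object@totalBaseCoverage), "\n")
})

#' @describeIn ScaledTrack-class display a short summary
#' @param object a \code{ScaledTrack}
#' @export
setMethod("show", "ScaledTrack", function(object) {
    nb <- sum(vapply(object@values, length, integer(1)))
    cat("ScaledTrack:", object@label, "\n",
        " binSize:", object@binSize, "bp ",
        " chromosomes:", length(object@values),
        " bins:", nb, "\n")
})

#' @describeIn GeneMarkTable-class display a short summary
#' @param object a \code{GeneMarkTable}
#' @export
setMethod("show", "GeneMarkTable", function(object) {
    cat("GeneMarkTable with", nrow(object@table), "genes\n")
    print(table(category = as.character(object@table$category)))
})
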