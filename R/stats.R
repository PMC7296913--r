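#' @importFrom stats phyper wilcox.test pchisq p.adjust pnorm var
#' @importFrom emmeans emmeans
NULL

#' Hypergeometric over-enrichment of a gene-set overlap
#'
#' Fold enrichment of the observed overlap of two gene sets over the overlap
#' expected by chance (\code{|A| * |B| / N}) within a finite universe, with
#' an upper-tail hypergeometric p-value \code{P[X >= observed]}.
#'
#' @param setA,setB character vectors of gene ids, non-empty subsets of
#'   \code{universe}.
#' @param universe character vector, the gene universe.
#' @return list with \code{n_universe}, \code{n_a}, \code{n_b},
#'   \code{n_overlap}, \code{expected}, \code{fold}, \code{p_value}.
#' @examples
#' hypergeometricEnrichment(letters[1:5], letters[c(1:4, 6:9)], letters[1:20])
#' @export
hypergeometricEnrichment <- function(setA, setB, universe) {
    if (length(universe) == 0L) stop("empty universe")
    setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
    if (length(setA) == 0L || length(setB) == 0L)
        stop("empty gene set: fold enrichment undefined")
    if (!all(setA %in% universe) || !all(setB %in% universe))
        stop("gene sets must be subsets of the universe")
    N <- length(universe); nA <- length(setA); nB <- length(setB)
    k <- length(intersect(setA, setB))
    expected <- nA * nB / N
    list(n_universe = N, n_a = nA, n_b = nB, n_overlap = k,
         expected = expected, fold = k / expected,
         p_value = phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE))
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with midrank tie
#' handling. The p-value is exact (label enumeration) for small tie-free
#' samples (\code{length(x) + length(y) <= 12}), otherwise the normal
#' approximation with continuity and tie correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with \code{U} (the statistic for \code{x}) and \code{p_value}.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mannWhitney <- function(x, y) {
    if (length(x) == 0L || length(y) == 0L) stop("empty input sample")
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !ties && (length(x) + length(y) <= 12L)
    res <- suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = TRUE))
    p <- res$p.value
    if (is.na(p)) p <- 1 # zero-variance case (all values tied)
    list(U = unname(res$statistic), p_value = p)
}

#' Chi-square test of up/down asymmetry
#'
#' One-degree-of-freedom Pearson chi-square of the observed numbers of up-
#' and downregulated genes against an equal split.
#'
#' @param nUp,nDown non-negative gene counts, not both zero.
#' @return list with \code{chi2} and \code{p_value}.
#' @examples
#' chisqUpDown(30, 10) # chi2 = 10
#' @export
chisqUpDown <- function(nUp, nDown) {
    total <- nUp + nDown
    if (total <= 0) stop("no deregulated genes: test undefined")
    expected <- total / 2
    chi2 <- (nUp - expected)^2 / expected + (nDown - expected)^2 / expected
    list(chi2 = chi2, p_value = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Bonferroni correction with a fixed family size
#'
#' \code{p_adj = min(1, p * m)} with a caller-specified family size
#' \code{m} (not inferred from the vector length).
#'
#' @param p numeric vector of p-values.
#' @param m family size (>= 1).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m) {
    if (m < 1) stop("'m' must be >= 1")
    pmin(1, p * m)
}

#' ANCOVA estimated marginal means of expression by mark presence
#'
#' Fits the additive two-factor linear model
#' \code{expression ~ h2aub + k27} (no interaction) on the fpkm scale and
#' returns the estimated marginal mean for each level of each factor,
#' averaging over the levels of the other factor with equal weight. Post hoc
#' pairwise contrasts between the four cells are Bonferroni-corrected with
#' a fixed family size (default m = 6, the number of pairwise comparisons of
#' four cells).
#'
#' @param expression named numeric vector (fpkm) over the gene universe.
#' @param h2aub,k27 named logical presence vectors over the same universe.
#' @param bonferroniM family size for the post hoc correction (default 6).
#' @return list with \code{emm} (data.frame: factor, level, emm, se) and
#'   \code{posthoc} (data.frame of pairwise cell contrasts with adjusted p).
#'   A design with an empty cell is fitted on the available cells with a
#'   warning.
#' @export
ancovaEmm <- function(expression, h2aub, k27, bonferroniM = 6) {
    stopifnot(!is.null(names(expression)))
    ids <- names(expression)
    if (!setequal(ids, names(h2aub)) || !setequal(ids, names(k27)))
        stop("expression and presence maps cover different gene universes")
    df <- data.frame(
        expr = unname(expression),
        h2aub = factor(ifelse(h2aub[ids], "present", "absent"),
                       levels = c("absent", "present")),
        k27 = factor(ifelse(k27[ids], "present", "absent"),
                     levels = c("absent", "present")))
    if (any(table(df$h2aub, df$k27) == 0L))
        warning("empty design cell: marginal means use the available cells only")
    fit <- lm(expr ~ h2aub + k27, data = df)
    emmRows <- lapply(c("h2aub", "k27"), function(fac) {
        em <- summary(emmeans(fit, fac))
        data.frame(factor = fac, level = as.character(em[[1]]),
                   emm = em$emmean, se = em$SE)
    })
    cells <- emmeans(fit, ~ h2aub + k27)
    ph <- summary(emmeans::contrast(cells, method = "pairwise"), adjust = "none")
    posthoc <- data.frame(contrast = as.character(ph$contrast),
                          estimate = ph$estimate,
                          p_value = ph$p.value,
                          p_adj = bonferroni(ph$p.value, bonferroniM))
    list(emm = do.call(rbind, emmRows), posthoc = posthoc, model = fit)
}

#' Threshold filtering of a differential-expression table
#'
#' Splits a DE table into up- and downregulated gene sets:
#' \code{up = log2FC >= lfcCutoff & p_adj < pCutoff & cpm_pass}, and
#' symmetrically for down. The conventional cutoffs are |log2FC| >= 1 with
#' adjusted p < 0.05; externally supplied tables analysed with a |log2FC|
#' cutoff of 4 keep that cutoff via \code{lfcCutoff = 4}.
#'
#' @param records data.frame with columns \code{gene_id}, \code{log2FC},
#'   \code{p_adj} and optionally \code{cpm_pass} (defaults to all TRUE).
#' @param lfcCutoff positive log2 fold-change cutoff (default 1).
#' @param pCutoff adjusted-p cutoff (default 0.05).
#' @return list with character vectors \code{up} and \code{down} (disjoint).
#' @export
deFilter <- function(records, lfcCutoff = 1, pCutoff = 0.05) {
    if (lfcCutoff <= 0) stop("'lfcCutoff' must be positive")
    cpm <- if ("cpm_pass" %in% colnames(records)) records$cpm_pass else TRUE
    keep <- !is.na(records$p_adj) & records$p_adj < pCutoff & cpm
    list(up = records$gene_id[keep & records$log2FC >= lfcCutoff],
         down = records$gene_id[keep & records$log2FC <= -lfcCutoff])
}

#' Responsiveness by mark category
#'
#' Gene responsiveness (the number of conditions in which a gene is
#' deregulated relative to control) summarized per mark category: median
#' score per category plus all pairwise two-sided Mann-Whitney tests between
#' categories, Bonferroni-corrected with fixed family size m (default 6, the
#' number of category pairs). Genes without a score are excluded; categories
#' with fewer than two scored genes are dropped with a warning.
#'
#' @param scores named numeric vector of responsiveness scores (possibly
#'   covering only part of the universe).
#' @param x a [GeneMarkTable-class].
#' @param bonferroniM family size for the correction (default 6).
#' @return list with \code{medians} (data.frame category, n, median) and
#'   \code{tests} (data.frame of pairwise comparisons).
#' @export
responsivenessByCategory <- function(scores, x, bonferroniM = 6) {
    stopifnot(is(x, "GeneMarkTable"))
    tab <- markTable(x)
    scored <- intersect(names(scores), tab$gene_id)
    cat <- as.character(tab$category[match(scored, tab$gene_id)])
    s <- unname(scores[scored])
    lev <- c("not_marked", "h2aub_only", "both", "k27_only")
    groups <- split(s, factor(cat, levels = lev))
    small <- vapply(groups, length, integer(1)) < 2L
    if (any(small)) {
        warning("categories with < 2 scored genes excluded: ",
                paste(names(groups)[small], collapse = ", "))
        groups <- groups[!small]
    }
    medians <- data.frame(category = names(groups),
                          n = vapply(groups, length, integer(1)),
                          median = vapply(groups, median, numeric(1)))
    pairsIdx <- utils::combn(names(groups), 2L, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairsIdx, function(pr) {
        mw <- mannWhitney(groups[[pr[1]]], groups[[pr[2]]])
        data.frame(group1 = pr[1], group2 = pr[2], U = mw$U,
                   p_value = mw$p_value,
                   p_adj = bonferroni(mw$p_value, bonferroniM))
    }))
    list(medians = medians, tests = tests)
}
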