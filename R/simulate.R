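#' @importFrom stats rpois runif rnorm rlnorm
NULL

#' Configuration for the synthetic miniature study
#'
#' Builds and validates the parameter set for [generateStudy()]. The
#' defaults define the package's reference study conditions: 200
#' non-overlapping genes on two chromosomes, two ChIP replicates per
#' antibody and genotype, 20 planted deubiquitinase-target genes whose
#' first-kilobase H2Aub1 fragment rate is elevated 8-fold in the mutant
#' (with a matching H3K27me3 loss where the gene is K27-marked), REF6
#' coverage coupled to the local H2Aub1 rate with a log10-log10 slope of
#' 0.4, CTCTGYTY motifs at 0.5 per kb including 3 planted clusters, and
#' responsiveness scores shifted upward for H2Aub1-marked genes.
#'
#' @param seed integer RNG seed; the same config and seed give
#'   byte-identical fixtures.
#' @param n_chroms,chrom_length chromosome count and length (bp).
#' @param n_genes number of genes (placed non-overlapping in equal slots).
#' @param gene_length_range min/max gene length (bp).
#' @param frac_h2aub,frac_k27,frac_both fractions of genes carrying H2Aub1
#'   only, H3K27me3 only, or both (must sum to <= 1).
#' @param n_targets planted UBP12/13 targets (H2Aub1 gain in the mutant).
#' @param n_loss planted genes losing H2Aub1 in the mutant (exercises
#'   down-direction differential peaks and the target subtraction rule).
#' @param enrichment_fold fragment-rate ratio of marked vs background
#'   regions, and of mutant vs wt at target first-kilobases.
#' @param background_rate background fragment-start rate (fragments per bp).
#' @param fragment_length fragment length (bp), fixed per study.
#' @param n_replicates ChIP replicates per antibody and genotype (H3
#'   control: one per genotype).
#' @param ref6_slope planted log10-log10 slope coupling REF6 to H2Aub1.
#' @param motif_density background CTCTGYTY motifs per kb.
#' @param n_clusters planted motif clusters (>= 4 motifs within 600 bp).
#' @param responsiveness_shift mean score offset for H2Aub1-marked genes.
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             n_chroms = 2L, chrom_length = 400000L,
                             n_genes = 200L,
                             gene_length_range = c(1000L, 3000L),
                             frac_h2aub = 0.10, frac_k27 = 0.18,
                             frac_both = 0.07,
                             n_targets = 20L, n_loss = 3L,
                             enrichment_fold = 8,
                             background_rate = 0.02,
                             fragment_length = 200L,
                             n_replicates = 2L,
                             ref6_slope = 0.4,
                             motif_density = 0.5,
                             n_clusters = 3L,
                             responsiveness_shift = 40) {
    cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                chrom_length = as.integer(chrom_length),
                n_genes = as.integer(n_genes),
                gene_length_range = as.integer(gene_length_range),
                frac_h2aub = frac_h2aub, frac_k27 = frac_k27,
                frac_both = frac_both,
                n_targets = as.integer(n_targets), n_loss = as.integer(n_loss),
                enrichment_fold = enrichment_fold,
                background_rate = background_rate,
                fragment_length = as.integer(fragment_length),
                n_replicates = as.integer(n_replicates),
                ref6_slope = ref6_slope, motif_density = motif_density,
                n_clusters = as.integer(n_clusters),
                responsiveness_shift = responsiveness_shift)
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a \code{SimulationConfig}.
#' @return invisibly \code{TRUE}; otherwise an error naming the violated
#'   invariant.
#' @export
validateSimulationConfig <- function(cfg) {
    fail <- function(what) stop("invalid SimulationConfig: ", what, call. = FALSE)
    if (cfg$frac_h2aub + cfg$frac_k27 + cfg$frac_both > 1)
        fail("frac_h2aub + frac_k27 + frac_both must be <= 1")
    if (cfg$n_targets > cfg$n_genes) fail("n_targets must be <= n_genes")
    if (cfg$n_targets < 0 || cfg$n_loss < 0) fail("gene counts must be >= 0")
    if (cfg$background_rate <= 0) fail("background_rate must be > 0")
    if (cfg$enrichment_fold <= 0) fail("enrichment_fold must be > 0")
    if (cfg$fragment_length < 1) fail("fragment_length must be >= 1")
    if (cfg$n_replicates < 1) fail("n_replicates must be >= 1")
    if (any(cfg$gene_length_range < 1) ||
        cfg$gene_length_range[1] > cfg$gene_length_range[2])
        fail("gene_length_range must be an increasing positive pair")
    slot <- (cfg$n_chroms * cfg$chrom_length) %/% cfg$n_genes
    if (slot < cfg$gene_length_range[2] + 200L)
        fail("genes cannot be placed non-overlapping: genome too small for n_genes")
    invisible(TRUE)
}

# fragment starts from a homogeneous Poisson process on [1, L - len + 1]
.poissonFragments <- function(chrom, L, rate, fragLen) {
    span <- L - fragLen + 1L
    n <- rpois(1L, rate * span)
    if (n == 0L) return(GRanges())
    starts <- sort(1L + floor(runif(n) * span))
    GRanges(chrom, IRanges(starts, width = fragLen))
}

# extra fragments over an enriched region: rate is *additional* starts/bp
.regionFragments <- function(region, addRate, fragLen, L) {
    n <- rpois(1L, addRate * width(region))
    if (n == 0L) return(GRanges())
    maxStart <- min(end(region), L - fragLen + 1L)
    starts <- sort(start(region) + floor(runif(n) * (maxStart - start(region) + 1L)))
    GRanges(as.character(seqnames(region)), IRanges(starts, width = fragLen))
}

# one ChIP library: background everywhere plus per-region Poisson enrichment
.simulateLibrary <- function(antibody, genotype, replicate, seqlengths,
                             regions, foldPerRegion, cfg) {
    frags <- lapply(names(seqlengths), function(chr) {
        bg <- .poissonFragments(chr, seqlengths[[chr]], cfg$background_rate,
                                cfg$fragment_length)
        idx <- which(as.character(seqnames(regions)) == chr)
        extra <- lapply(idx, function(i) {
            add <- (foldPerRegion[i] - 1) * cfg$background_rate
            if (add <= 0) return(NULL)
            .regionFragments(regions[i], add, cfg$fragment_length,
                             seqlengths[[chr]])
        })
        extra <- extra[!vapply(extra, is.null, logical(1))]
        suppressWarnings(do.call(c, c(list(bg), extra)))
    })
    gr <- GenomicRanges::sort(suppressWarnings(do.call(c, frags)))
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
    FragmentLibrary(gr, antibody, genotype, as.integer(replicate))
}

# REF6 library: per 50-bp bin, expected fragment-start rate follows
# 10^(intercept + slope * log10(local H2Aub1 start rate))
.simulateRef6Library <- function(genotype, replicate, seqlengths,
                                 h2aubRegions, h2aubFold, cfg) {
    slope <- cfg$ref6_slope
    intercept <- (1 - slope) * log10(cfg$background_rate)
    binSize <- 50L
    frags <- lapply(names(seqlengths), function(chr) {
        L <- seqlengths[[chr]]
        nBins <- ceiling(L / binSize)
        binStart <- (seq_len(nBins) - 1L) * binSize + 1L
        binEnd <- pmin(binStart + binSize - 1L, L)
        rate <- rep(cfg$background_rate, nBins)
        idx <- which(as.character(seqnames(h2aubRegions)) == chr)
        for (i in idx) {
            hit <- binStart <= end(h2aubRegions)[i] & binEnd >= start(h2aubRegions)[i]
            rate[hit] <- cfg$background_rate * h2aubFold[i]
        }
        ref6Rate <- 10^(intercept + slope * log10(rate))
        counts <- rpois(nBins, ref6Rate * (binEnd - binStart + 1L))
        total <- sum(counts)
        if (total == 0L) return(GRanges())
        starts <- rep(binStart, counts) +
            floor(runif(total) * rep(binEnd - binStart + 1L, counts))
        starts <- pmin(starts, L - cfg$fragment_length + 1L)
        GRanges(chr, IRanges(sort(starts), width = cfg$fragment_length))
    })
    gr <- GenomicRanges::sort(suppressWarnings(do.call(c, frags)))
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
    FragmentLibrary(gr, "REF6", genotype, as.integer(replicate))
}

# jittered "called" peaks from true enriched regions (boundary noise only)
.jitterPeaks <- function(regions, seqlengths, sd = 30) {
    if (length(regions) == 0L) return(granges(regions))
    s <- pmax(1L, start(regions) + as.integer(round(rnorm(length(regions), 0, sd))))
    e <- end(regions) + as.integer(round(rnorm(length(regions), 0, sd)))
    e <- pmax(e, s + 99L) # keep a sensible minimum width
    e <- pmin(e, seqlengths[as.character(seqnames(regions))])
    GRanges(seqnames(regions), IRanges(s, e))
}

#' Simulate a chromosome sequence with implanted CTCTGYTY motifs
#'
#' Random uniform A/C/G/T background with motif instances (Y drawn from
#' \{C, T\}, random strand) implanted at recorded positions: background
#' motifs at \code{motifDensity} per kb plus \code{nClusters} clusters of
#' 4-6 motifs within a 600-bp window. Implanted instances never overlap.
#' Note that the background sequence can also contain chance matches, so the
#' authoritative hit list for a simulated genome is a rescan with
#' [scanMotifs()].
#'
#' @param length chromosome length (bp).
#' @param motifDensity background motifs per kb.
#' @param nClusters number of planted clusters.
#' @param chrom chromosome name used in the returned coordinates.
#' @param window cluster window (bp, default 600).
#' @return list with \code{sequence} (\code{DNAString}), \code{planted}
#'   (\code{GRanges} of implanted instances) and \code{clusters}
#'   (\code{GRanges} spanning each planted cluster).
#' @export
simulateMotifSequence <- function(length, motifDensity = 0.5, nClusters = 0L,
                                  chrom = "chr1", window = 600L) {
    L <- as.integer(length)
    nBackground <- as.integer(round(motifDensity * L / 1000))
    if (nBackground + nClusters * 6L > L %/% 20L)
        stop("infeasible motif placement: density too high for sequence length")
    seq <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    positions <- integer(0)
    # planted clusters: 4-6 motifs whose extent fits the window
    clusterSpans <- GRanges()
    if (nClusters > 0L) {
        segment <- L %/% nClusters
        if (segment < window + 200L)
            stop("infeasible motif placement: too many clusters for sequence length")
        for (ci in seq_len(nClusters)) {
            k <- sample(4:6, 1L)
            anchor <- (ci - 1L) * segment + 100L +
                floor(runif(1) * (segment - window - 200L))
            offs <- sort(sample(seq(0L, window - 8L, by = 12L), k))
            pos <- anchor + offs
            positions <- c(positions, pos)
            clusterSpans <- c(clusterSpans,
                              GRanges(chrom, IRanges(min(pos), max(pos) + 7L)))
        }
    }
    if (nBackground > 0L) {
        cand <- sort(sample.int(L - 8L, min(L - 8L, nBackground * 3L)))
        keep <- c(TRUE, diff(cand) >= 12L)
        cand <- cand[keep]
        # drop background candidates colliding with cluster motifs
        if (length(positions))
            cand <- cand[vapply(cand, function(p)
                all(abs(p - positions) >= 12L), logical(1))]
        if (length(cand) < nBackground)
            stop("infeasible motif placement: could not place background motifs")
        positions <- c(positions, sort(sample(cand, nBackground)))
    }
    positions <- sort(positions)
    if (length(positions) == 0L)
        return(list(sequence = DNAString(paste(seq, collapse = "")),
                    planted = GRanges(), clusters = clusterSpans))
    strands <- sample(c("+", "-"), length(positions), replace = TRUE)
    planted <- GRanges(chrom, IRanges(positions, width = 8L), strand = strands)
    for (i in seq_along(positions)) {
        ys <- sample(c("C", "T"), 2L, replace = TRUE)
        inst <- c("C", "T", "C", "T", "G", ys[1], "T", ys[2])
        if (strands[i] == "-")
            inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
        seq[positions[i]:(positions[i] + 7L)] <- inst
    }
    list(sequence = DNAString(paste(seq, collapse = "")),
         planted = planted, clusters = clusterSpans)
}

#' Generate a complete synthetic miniature study
#'
#' Produces, from one [simulationConfig()], every input of the downstream
#' pipeline with known ground truth: a genome with implanted CTCTGYTY
#' motifs, non-overlapping gene models, per-replicate fragment libraries for
#' H2Aub1 / H3K27me3 / REF6 (plus one flat H3 control per genotype) in wt
#' and mutant, jittered "called" peaks per replicate, a
#' differential-expression table with planted fold changes, and
#' responsiveness scores positively shifted for H2Aub1-marked genes.
#'
#' Planted effects: target genes' first-kilobase H2Aub1 fragment rate is
#' multiplied by \code{enrichment_fold} in the mutant; K27-marked targets
#' lose their H3K27me3 enrichment there; \code{n_loss} H2Aub1-marked genes
#' lose H2Aub1 in the mutant; REF6 per-bin rates follow the planted
#' log10-log10 coupling to the local (genotype-specific) H2Aub1 rate;
#' targets are planted as upregulated in the DE table.
#'
#' @param cfg a \code{SimulationConfig}. The RNG seed is taken from
#'   \code{cfg$seed}; identical config gives byte-identical fixtures.
#' @return a list of class \code{StudyFixture} with elements
#'   \code{config}, \code{seqlengths}, \code{genome} (DNAStringSet),
#'   \code{genes} (GRanges with gene_id/biotype), \code{libraries} (named
#'   list of [FragmentLibrary-class]), \code{peaks} (named list of GRanges,
#'   one per antibody x genotype x replicate), \code{h2aubSummits}
#'   (GRanges), \code{deTable} (data.frame), \code{responsiveness} (named
#'   numeric) and \code{groundTruth}.
#' @export
generateStudy <- function(cfg = simulationConfig()) {
    validateSimulationConfig(cfg)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(cfg$seed)

    seqlengths <- setNames(rep(cfg$chrom_length, cfg$n_chroms),
                           paste0("chr", seq_len(cfg$n_chroms)))

    ## genome sequence with motifs
    motif <- lapply(names(seqlengths), function(chr)
        simulateMotifSequence(seqlengths[[chr]], cfg$motif_density,
                              if (chr == names(seqlengths)[1]) cfg$n_clusters else 0L,
                              chrom = chr))
    genome <- DNAStringSet(lapply(motif, `[[`, "sequence"))
    names(genome) <- names(seqlengths)
    plantedClusters <- suppressWarnings(do.call(c, lapply(motif, `[[`, "clusters")))
    motifHits <- scanMotifs(genome) # authoritative: rescan of the fasta

    ## non-overlapping gene placement in equal slots
    perChrom <- ceiling(cfg$n_genes / cfg$n_chroms)
    slots <- data.frame(
        chrom = rep(names(seqlengths), each = perChrom),
        slotStart = rep((seq_len(perChrom) - 1L), cfg$n_chroms))
    slots <- slots[seq_len(cfg$n_genes), ]
    slotWidth <- cfg$chrom_length %/% perChrom
    lens <- as.integer(round(runif(cfg$n_genes, cfg$gene_length_range[1],
                                   cfg$gene_length_range[2])))
    offs <- as.integer(floor(runif(cfg$n_genes) *
                             (slotWidth - lens - 100L))) + 50L
    starts <- slots$slotStart * slotWidth + offs
    genes <- GRanges(slots$chrom, IRanges(starts + 1L, width = lens),
                     strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE))
    GenomeInfoDb::seqlevels(genes) <- names(seqlengths)
    GenomeInfoDb::seqlengths(genes) <- seqlengths
    genes$gene_id <- sprintf("gene%04d", seq_len(cfg$n_genes))
    genes$biotype <- "protein_coding"

    ## mark assignment and planted gene sets
    nBoth <- round(cfg$frac_both * cfg$n_genes)
    nH2 <- round(cfg$frac_h2aub * cfg$n_genes)
    nK27 <- round(cfg$frac_k27 * cfg$n_genes)
    cats <- sample(c(rep("both", nBoth), rep("h2aub_only", nH2),
                     rep("k27_only", nK27),
                     rep("not_marked", cfg$n_genes - nBoth - nH2 - nK27)))
    names(cats) <- genes$gene_id
    h2aubMarked <- cats %in% c("both", "h2aub_only")
    k27Marked <- cats %in% c("both", "k27_only")

    # targets gain H2Aub1 in the mutant, so they are drawn from genes
    # without wt H2Aub1; about three quarters carry H3K27me3 (PRC2 targets)
    k27Pool <- genes$gene_id[cats == "k27_only"]
    plainPool <- genes$gene_id[cats == "not_marked"]
    nTargetK27 <- min(round(0.74 * cfg$n_targets), length(k27Pool))
    if (cfg$n_targets - nTargetK27 > length(plainPool))
        stop("invalid SimulationConfig: not enough unmarked genes to plant targets")
    targets <- c(sample(k27Pool, nTargetK27),
                 sample(plainPool, cfg$n_targets - nTargetK27))
    targets <- sort(targets)
    lossPool <- setdiff(genes$gene_id[h2aubMarked], targets)
    lossGenes <- sort(sample(lossPool, min(cfg$n_loss, length(lossPool))))

    ## per-gene fragment-rate folds over the first 1 kb; marked genes carry
    ## gene-to-gene enrichment variation (as real ChIP peaks do), which also
    ## spreads the A axis of the common peaks the M-A normalization is fit on
    first1kb <- deriveRegion(genes, "first_1kb")
    isTarget <- genes$gene_id %in% targets
    isLoss <- genes$gene_id %in% lossGenes
    fold <- cfg$enrichment_fold
    jitterH2 <- pmax(1.5, fold * 2^rnorm(cfg$n_genes, 0, 0.75))
    jitterK27 <- pmax(1.5, fold * 2^rnorm(cfg$n_genes, 0, 0.75))
    h2WtFold <- ifelse(h2aubMarked, jitterH2, 1)
    # targets: mutant rate = enrichment_fold x the wt rate, exactly
    h2MutFold <- h2WtFold * ifelse(isTarget, fold, 1)
    h2MutFold[isLoss] <- 1 # planted loss of H2Aub1
    k27WtFold <- ifelse(k27Marked, jitterK27, 1)
    k27MutFold <- ifelse(isTarget & k27Marked, 1, k27WtFold) # planted K27 loss

    ## fragment libraries
    libs <- list()
    for (gt in c("wt", "mutant")) {
        h2Fold <- if (gt == "wt") h2WtFold else h2MutFold
        k27Fold <- if (gt == "wt") k27WtFold else k27MutFold
        for (r in seq_len(cfg$n_replicates)) {
            libs[[sprintf("H2Aub1_%s_rep%d", gt, r)]] <-
                .simulateLibrary("H2Aub1", gt, r, seqlengths, first1kb, h2Fold, cfg)
            libs[[sprintf("H3K27me3_%s_rep%d", gt, r)]] <-
                .simulateLibrary("H3K27me3", gt, r, seqlengths, first1kb, k27Fold, cfg)
            libs[[sprintf("REF6_%s_rep%d", gt, r)]] <-
                .simulateRef6Library(gt, r, seqlengths, first1kb, h2Fold, cfg)
        }
        libs[[sprintf("H3_%s_rep1", gt)]] <-
            .simulateLibrary("H3", gt, 1L, seqlengths, first1kb[0],
                             numeric(0), cfg)
    }

    ## jittered called peaks (per antibody x genotype x replicate)
    peaks <- list()
    trueRegions <- list(
        H2Aub1_wt = first1kb[h2WtFold > 1], H2Aub1_mutant = first1kb[h2MutFold > 1],
        H3K27me3_wt = first1kb[k27WtFold > 1], H3K27me3_mutant = first1kb[k27MutFold > 1],
        REF6_wt = first1kb[h2WtFold > 1], REF6_mutant = first1kb[h2MutFold > 1])
    for (nm in names(trueRegions)) {
        for (r in seq_len(cfg$n_replicates)) {
            peaks[[sprintf("%s_rep%d", nm, r)]] <-
                .jitterPeaks(trueRegions[[nm]], seqlengths)
        }
    }
    # narrow-mode style summits for the wt H2Aub1 peaks (replicates merged)
    h2WtRegions <- trueRegions$H2Aub1_wt
    h2aubSummits <- GRanges(seqnames(h2WtRegions),
                            IRanges((start(h2WtRegions) + end(h2WtRegions)) %/% 2L,
                                    width = 1L))

    ## differential-expression table with planted fold changes
    # up/down asymmetry among non-target genes (roughly 3:1, as in typical
    # derepression mutants), capped by the genes still unassigned
    free <- setdiff(genes$gene_id, c(targets, lossGenes))
    nUpExtra <- min(30L, as.integer(round(0.15 * cfg$n_genes)),
                    length(free) %/% 2L)
    nDownExtra <- min(10L, as.integer(round(0.05 * cfg$n_genes)),
                      length(free) %/% 4L)
    upExtra <- sample(free, nUpExtra)
    downExtra <- sample(setdiff(free, upExtra), nDownExtra)
    plantedLfc <- setNames(rep(0, cfg$n_genes), genes$gene_id)
    plantedLfc[targets] <- 2
    plantedLfc[upExtra] <- 1.5
    plantedLfc[downExtra] <- -1.5
    wtFpkm <- pmax(0.1, 5 + 3 * h2aubMarked - 2 * k27Marked +
                   rnorm(cfg$n_genes, 0, 1.5))
    names(wtFpkm) <- genes$gene_id
    depth <- 20
    nReps <- 3L
    deTable <- do.call(rbind, lapply(seq_len(cfg$n_genes), function(i) {
        gid <- genes$gene_id[i]
        muWt <- wtFpkm[[gid]] * depth
        muMut <- muWt * 2^plantedLfc[[gid]]
        cw <- rpois(nReps, muWt); cm <- rpois(nReps, muMut)
        lw <- log2(cw + 1); lmu <- log2(cm + 1)
        se <- sqrt(var(lw) / nReps + var(lmu) / nReps) + 0.05
        z <- (mean(lmu) - mean(lw)) / se
        detected <- any(cw > 0) || any(cm > 0)
        data.frame(gene_id = gid,
                   log2FC = if (detected) mean(lmu) - mean(lw) else 0,
                   p_value = 2 * pnorm(-abs(z)),
                   baseMean = mean(c(cw, cm)),
                   detected = detected,
                   cpm_pass = sum(cw >= 2) >= 2L || sum(cm >= 2) >= 2L)
    }))
    deTable$p_adj <- p.adjust(deTable$p_value, method = "BH")

    ## responsiveness scores, shifted for H2Aub1-marked genes
    responsiveness <- setNames(
        rpois(cfg$n_genes, 60 + cfg$responsiveness_shift * h2aubMarked),
        genes$gene_id)

    groundTruth <- list(
        target_genes = targets, loss_genes = lossGenes,
        mark_assignment = cats,
        motif_positions = motifHits, cluster_positions = plantedClusters,
        planted_ref6_slope = cfg$ref6_slope, planted_de = plantedLfc,
        enriched_regions = trueRegions)

    structure(list(config = cfg, seqlengths = seqlengths, genome = genome,
                   genes = genes, libraries = libs, peaks = peaks,
                   h2aubSummits = h2aubSummits, deTable = deTable,
                   responsiveness = responsiveness, groundTruth = groundTruth),
              class = "StudyFixture")
}

#' Simulate paired H2Aub1/REF6 libraries with a planted log-log coupling
#'
#' Dedicated fixture for the windowed REF6~H2Aub1 regression: one
#' chromosome partitioned into constant-rate blocks whose H2Aub1
#' fragment-start rate is log10-normal, with the REF6 rate following
#' \code{10^(intercept + slope * log10(h2aub rate))} exactly, plus motif
#' hits placed independently of both rates (so motif-count strata share the
#' planted slope). Block-level (rather than bin-level) rate variation keeps
#' the fragment-level Poisson noise small relative to the planted signal,
#' so the regression slope on 50-bp bins is recoverable.
#'
#' @param nBins number of 50-bp bins (default 50000).
#' @param binSize bin width (bp).
#' @param blockSize width of constant-rate blocks (bp, default 1000).
#' @param meanLog10Rate,sdLog10Rate log10-normal parameters of the block
#'   H2Aub1 start rate (fragments per bp).
#' @param slope planted log10-log10 slope (default 0.4).
#' @param fragmentLength fragment length (bp, default 100).
#' @param motifDensity motifs per kb placed uniformly at random.
#' @param seed RNG seed.
#' @return list with \code{h2aub} and \code{ref6}
#'   ([FragmentLibrary-class]), \code{seqlengths}, \code{motifHits}
#'   (GRanges) and \code{plantedSlope}.
#' @export
simulateRef6Coupling <- function(nBins = 50000L, binSize = 50L,
                                 blockSize = 1000L,
                                 meanLog10Rate = -0.4, sdLog10Rate = 0.4,
                                 slope = 0.4, fragmentLength = 100L,
                                 motifDensity = 0.5, seed = 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    L <- as.integer(nBins) * as.integer(binSize)
    seqlengths <- c(chr1 = L)
    nBlocks <- ceiling(L / blockSize)
    log10Rate <- rnorm(nBlocks, meanLog10Rate, sdLog10Rate)
    intercept <- (1 - slope) * meanLog10Rate # matches the overall scale
    rates <- list(h2aub = 10^log10Rate,
                  ref6 = 10^(intercept + slope * log10Rate))
    mkLib <- function(rate, ab) {
        counts <- rpois(nBlocks, rate * blockSize)
        total <- sum(counts)
        blockStart <- (seq_len(nBlocks) - 1L) * blockSize + 1L
        starts <- rep(blockStart, counts) +
            floor(runif(total) * blockSize)
        starts <- pmin(starts, L - fragmentLength + 1L)
        gr <- GRanges("chr1", IRanges(sort(starts), width = fragmentLength))
        GenomeInfoDb::seqlengths(gr) <- seqlengths
        FragmentLibrary(gr, ab, "wt", 1L)
    }
    h2aub <- mkLib(rates$h2aub, "H2Aub1")
    ref6 <- mkLib(rates$ref6, "REF6")
    nMotifs <- as.integer(round(motifDensity * L / 1000))
    motifHits <- GRanges("chr1",
                         IRanges(sort(sample.int(L - 8L, nMotifs)), width = 8L))
    list(h2aub = h2aub, ref6 = ref6, seqlengths = seqlengths,
         motifHits = motifHits, plantedSlope = slope)
}
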