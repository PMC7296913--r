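#' @importFrom tools md5sum
NULL

#' Pipeline configuration for a study directory
#'
#' Builds the configuration consumed by [runPipeline()] from a study
#' directory laid out as written by [writeStudy()] (genome FASTA, gene
#' GFF3, \code{fragments/<Antibody>_<genotype>_rep<k>.bed},
#' \code{peaks/<Antibody>_<genotype>_rep<k>.broadPeak}, DE and
#' responsiveness TSVs). All analysis parameters carry the standard
#' defaults: 50-bp bins, 1000-bp peak-count windows, p < 0.05 with m-cutoff
#' 0 for differential peaks, 600-bp / 4-motif clusters, |log2FC| >= 1 with
#' adjusted p < 0.05 for the DE filter, and Bonferroni family size 6.
#'
#' @param dir study directory.
#' @param nReplicates replicates per antibody and genotype (default 2).
#' @param seed RNG seed used for the normalization bootstrap.
#' @param ... parameter overrides (\code{bin_size}, \code{window_size},
#'   \code{motif_window}, \code{min_motifs}, \code{p_cutoff},
#'   \code{m_cutoff}, \code{lfc_cutoff}, \code{bonferroni_m},
#'   \code{n_simulations}).
#' @return a list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(dir, nReplicates = 2L, seed = 1L, ...) {
    params <- list(bin_size = 50L, window_size = 1000L, motif_window = 600L,
                   min_motifs = 4L, p_cutoff = 0.05, m_cutoff = 0,
                   lfc_cutoff = 1, bonferroni_m = 6, n_simulations = 100L)
    over <- list(...)
    params[names(over)] <- over
    libs <- expand.grid(antibody = c("H2Aub1", "H3K27me3", "REF6"),
                        genotype = c("wt", "mutant"),
                        replicate = seq_len(nReplicates),
                        stringsAsFactors = FALSE)
    libs$path <- file.path(dir, "fragments",
                           sprintf("%s_%s_rep%d.bed", libs$antibody,
                                   libs$genotype, libs$replicate))
    peaks <- libs
    peaks$path <- file.path(dir, "peaks",
                            sprintf("%s_%s_rep%d.broadPeak", peaks$antibody,
                                    peaks$genotype, peaks$replicate))
    cfg <- list(genome = file.path(dir, "genome.fa"),
                genes = file.path(dir, "genes.gff3"),
                libraries = libs, peaks = peaks,
                de_table = file.path(dir, "de_table.tsv"),
                responsiveness = file.path(dir, "responsiveness.tsv"),
                params = params, seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

.checkPipelineConfig <- function(config) {
    paths <- c(config$genome, config$genes, config$libraries$path,
               config$peaks$path, config$de_table, config$responsiveness)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("pipeline configuration error: missing input file(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    for (ab in c("H2Aub1", "H3K27me3")) {
        for (gt in c("wt", "mutant")) {
            n <- sum(config$libraries$antibody == ab & config$libraries$genotype == gt)
            if (n < 2L)
                stop("pipeline configuration error: ", ab, " ", gt,
                     " needs >= 2 replicates for concordance filtering",
                     call. = FALSE)
        }
    }
    invisible(TRUE)
}

.stageLog <- function(log, stage, ...) {
    line <- sprintf("[%s] %s", stage, paste0(...))
    c(log, line)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on the inputs named by the
#' configuration: coverage-scaled tracks and replicate averaging,
#' M-A differential H2Aub1 peaks per replicate with concordance filtering,
#' target-gene definition (H2Aub1 gain minus loss), H3K27me3 differential
#' peaks and PRC1-dependency classification, mark presence and four-way
#' categorization, motif scanning / clusters / windowed REF6 regression, and
#' the statistical summaries (DE filter with chi-square up/down asymmetry,
#' hypergeometric overlap of targets with upregulated genes, ANCOVA
#' estimated marginal means, responsiveness by category). Reruns with
#' identical inputs and seed are bit-identical.
#'
#' @param config a \code{PipelineConfig} from [pipelineConfig()].
#' @param outDir output directory for result files; \code{NULL} skips
#'   writing and only returns the result list.
#' @return (invisibly when writing) a list with the per-stage results and a
#'   \code{summary} element (the machine-readable run summary).
#' @export
runPipeline <- function(config, outDir = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    .checkPipelineConfig(config)
    p <- config$params
    log <- character(0)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)

    stage <- "load"
    res <- tryCatch({
        genome <- readDNAStringSet(config$genome)
        names(genome) <- sub("\\s.*$", "", names(genome))
        seqlengths <- setNames(Biostrings::width(genome), names(genome))
        genes <- readGenesGff3(config$genes)
        GenomeInfoDb::seqlevels(genes) <- names(seqlengths)
        GenomeInfoDb::seqlengths(genes) <- seqlengths
        libs <- list()
        for (i in seq_len(nrow(config$libraries))) {
            row <- config$libraries[i, ]
            id <- sprintf("%s_%s_rep%d", row$antibody, row$genotype, row$replicate)
            libs[[id]] <- readFragmentBed(row$path, row$antibody, row$genotype,
                                          row$replicate, seqlengths)
        }
        peakSets <- list()
        for (i in seq_len(nrow(config$peaks))) {
            row <- config$peaks[i, ]
            id <- sprintf("%s_%s_rep%d", row$antibody, row$genotype, row$replicate)
            peakSets[[id]] <- readBroadPeak(row$path)
        }
        deTable <- read.table(config$de_table, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
        resp <- read.table(config$responsiveness, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
        responsiveness <- setNames(resp$score, resp$gene_id)
        log <- .stageLog(log, stage, length(genes), " genes, ",
                         length(libs), " libraries, ",
                         length(peakSets), " peak sets")

        stage <- "tracks"
        tracks <- lapply(libs, binTrack, seqlengths = seqlengths,
                         binSize = p$bin_size)
        avgTrack <- function(ab, gt) {
            ids <- grep(sprintf("^%s_%s_rep", ab, gt), names(tracks), value = TRUE)
            averageReplicates(tracks[ids], label = paste(ab, gt))
        }
        h2aubWt <- avgTrack("H2Aub1", "wt")
        ref6Wt <- avgTrack("REF6", "wt")
        log <- .stageLog(log, stage, length(tracks), " binned tracks (bin ",
                         p$bin_size, " bp)")

        stage <- "diffpeaks"
        nrep <- max(config$libraries$replicate)
        diffFor <- function(ab) {
            reps <- lapply(seq_len(nrep), function(r) {
                differentialPeaks(
                    peakSets[[sprintf("%s_mutant_rep%d", ab, r)]],
                    peakSets[[sprintf("%s_wt_rep%d", ab, r)]],
                    libs[[sprintf("%s_mutant_rep%d", ab, r)]],
                    libs[[sprintf("%s_wt_rep%d", ab, r)]],
                    windowSize = p$window_size,
                    nSimulations = p$n_simulations,
                    pCutoff = p$p_cutoff, mCutoff = p$m_cutoff)
            })
            Reduce(concordantDifferentialPeaks, reps)
        }
        h2aubDiffPeaks <- diffFor("H2Aub1")
        k27DiffPeaks <- diffFor("H3K27me3")
        log <- .stageLog(log, stage, length(h2aubDiffPeaks),
                         " concordant H2Aub1 / ", length(k27DiffPeaks),
                         " H3K27me3 differential peaks")

        stage <- "targets"
        upPeaks <- h2aubDiffPeaks[h2aubDiffPeaks$direction == "up"]
        downPeaks <- h2aubDiffPeaks[h2aubDiffPeaks$direction == "down"]
        targets <- defineUbpTargets(upPeaks, downPeaks, genes)
        log <- .stageLog(log, stage, length(targets), " target genes")

        stage <- "classify"
        h2aubReal <- intersectReplicates(peakSets[["H2Aub1_wt_rep1"]],
                                         peakSets[["H2Aub1_wt_rep2"]])
        k27Real <- intersectReplicates(peakSets[["H3K27me3_wt_rep1"]],
                                       peakSets[["H3K27me3_wt_rep2"]])
        h2aubPresence <- callMarkPresence(h2aubReal, genes)
        k27Presence <- callMarkPresence(k27Real, genes)
        isTarget <- setNames(genes$gene_id %in% targets, genes$gene_id)
        markTab <- categorizeMarks(h2aubPresence, k27Presence,
                                   isTarget = isTarget)
        k27Down <- k27DiffPeaks[k27DiffPeaks$direction == "down"]
        prc1 <- classifyPrc1Dependency(k27Presence, k27Down, genes)
        log <- .stageLog(log, stage,
                         paste(categoryCounts(markTab)$n, collapse = "/"),
                         " genes per category")

        stage <- "motifs"
        motifHits <- scanMotifs(genome)
        clusters <- findMotifClusters(motifHits, window = p$motif_window,
                                      minMotifs = p$min_motifs)
        windows <- windowTable(h2aubWt, ref6Wt, motifHits,
                               motifWindow = p$motif_window)
        regression <- h2aubRef6Regression(windows)
        log <- .stageLog(log, stage, length(motifHits), " motifs, ",
                         length(clusters), " clusters")

        stage <- "stats"
        de <- deFilter(deTable, lfcCutoff = p$lfc_cutoff, pCutoff = p$p_cutoff)
        asym <- chisqUpDown(length(de$up), length(de$down))
        overlap <- if (length(targets) && length(de$up))
            hypergeometricEnrichment(targets, de$up, genes$gene_id) else NULL
        expr <- setNames(deTable$baseMean, deTable$gene_id)
        emm <- ancovaEmm(expr[genes$gene_id], h2aubPresence, k27Presence,
                         bonferroniM = p$bonferroni_m)
        respSummary <- responsivenessByCategory(responsiveness, markTab,
                                                bonferroniM = p$bonferroni_m)
        targetK27Fraction <- if (length(targets))
            categoryFraction(targets, markTab, "k27") else NA_real_
        log <- .stageLog(log, stage, length(de$up), " up / ",
                         length(de$down), " down DE genes")

        summary <- list(
            n_genes = length(genes),
            category_counts = setNames(as.list(categoryCounts(markTab)$n),
                                       categoryCounts(markTab)$category),
            n_up_diff_peaks = length(upPeaks),
            n_down_diff_peaks = length(downPeaks),
            targets = targets,
            n_targets = length(targets),
            target_k27_fraction = targetK27Fraction,
            prc1_class_counts = as.list(table(prc1)),
            n_motifs = length(motifHits),
            n_motif_clusters = length(clusters),
            regression = if (!is.null(regression)) regression else list(),
            de_up = length(de$up), de_down = length(de$down),
            chisq_updown = asym,
            target_de_overlap = overlap,
            emm = emm$emm,
            responsiveness_medians = respSummary$medians,
            parameters = p, seed = config$seed)

        list(genes = genes, tracks = tracks,
             h2aubDiffPeaks = h2aubDiffPeaks, k27DiffPeaks = k27DiffPeaks,
             targets = targets, markTable = markTab, prc1Class = prc1,
             motifHits = motifHits, clusters = clusters,
             windowTable = windows, regression = regression,
             deSets = de, emm = emm, responsiveness = respSummary,
             summary = summary, log = log)
    }, error = function(e) {
        stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
             call. = FALSE)
    })

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(res$summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = 10, pretty = TRUE)
        writeDifferentialPeaks(res$h2aubDiffPeaks,
                               file.path(outDir, "h2aub_differential_peaks.bed"))
        writeDifferentialPeaks(res$k27DiffPeaks,
                               file.path(outDir, "k27_differential_peaks.bed"))
        write.table(data.frame(gene_id = res$targets),
                    file.path(outDir, "targets.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        tab <- as.data.frame(markTable(res$markTable))
        tab$prc1_class <- unname(res$prc1Class[tab$gene_id])
        write.table(tab, file.path(outDir, "mark_table.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(res$regression))
            write.table(res$regression, file.path(outDir, "ref6_regression.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(res$log, file.path(outDir, "run.log"))
        return(invisible(res))
    }
    res
}
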