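#' @importFrom rtracklayer import export
#' @importFrom utils read.table write.table
#' @importFrom Biostrings writeXStringSet readDNAStringSet
NULL

#' Read gene models from GFF3
#'
#' Imports \code{gene}-type features; gene ids come from the \code{ID}
#' attribute and biotypes from \code{biotype} (defaulting to
#' \code{protein_coding} when absent).
#'
#' @param path GFF3 file.
#' @param proteinCodingOnly keep only protein-coding genes (default TRUE).
#' @return \code{GRanges} with \code{gene_id} and \code{biotype} columns.
#' @export
readGenesGff3 <- function(path, proteinCodingOnly = TRUE) {
    gr <- import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    genes <- granges(gr)
    genes$gene_id <- gr$ID
    genes$biotype <- if (!is.null(gr$biotype)) gr$biotype else "protein_coding"
    if (proteinCodingOnly) genes <- genes[genes$biotype == "protein_coding"]
    genes
}

#' Write gene models as GFF3
#' @param genes \code{GRanges} with \code{gene_id} and \code{biotype}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGenesGff3 <- function(genes, path) {
    out <- granges(genes)
    mcols(out) <- DataFrame(source = "h2aubDiff", type = "gene",
                            ID = genes$gene_id, biotype = genes$biotype)
    export(out, path, format = "gff3")
    invisible(path)
}

#' Read a fragment BED file into a FragmentLibrary
#'
#' @param path BED file of fragment intervals.
#' @param antibody,genotype,replicate library metadata.
#' @param seqlengths optional named chromosome lengths to attach.
#' @return a [FragmentLibrary-class].
#' @export
readFragmentBed <- function(path, antibody, genotype, replicate = 1L,
                            seqlengths = NULL) {
    gr <- import(path, format = "BED")
    gr <- granges(gr, use.mcols = FALSE)
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    FragmentLibrary(gr, antibody, genotype, replicate)
}

#' Write fragment intervals as BED6
#' @param lib a [FragmentLibrary-class].
#' @param path output BED file.
#' @return invisibly, \code{path}.
#' @export
writeFragmentBed <- function(lib, path) {
    export(fragments(lib), path, format = "BED")
    invisible(path)
}

# shared reader: broadPeak (6+3) and narrowPeak (6+4, summit offset col 10)
.readPeakTable <- function(path, extra) {
    cols <- c("chrom", "start", "end", "name", "score", "strand", extra)
    df <- read.table(path, sep = "\t", header = FALSE, col.names = cols,
                     stringsAsFactors = FALSE)
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*"))
    for (e in extra) mcols(gr)[[e]] <- df[[e]]
    gr
}

#' Read MACS2-style peak files
#'
#' \code{readBroadPeak} reads the 9-column broadPeak format;
#' \code{readNarrowPeak} the 10-column narrowPeak format, adding a
#' \code{summit} metadata column with the absolute 1-based summit position
#' (\code{start + peak-offset column}).
#'
#' @param path peak file.
#' @return \code{GRanges} with the format's score columns as metadata.
#' @export
readBroadPeak <- function(path) {
    .readPeakTable(path, c("signalValue", "pValue", "qValue"))
}

#' @rdname readBroadPeak
#' @export
readNarrowPeak <- function(path) {
    gr <- .readPeakTable(path, c("signalValue", "pValue", "qValue", "peak"))
    mcols(gr)$summit <- start(gr) + mcols(gr)$peak
    gr
}

#' Write peaks in broadPeak / narrowPeak format
#'
#' @param peaks \code{GRanges}; for narrowPeak, a \code{summit} metadata
#'   column (absolute 1-based position) provides column 10, otherwise the
#'   peak midpoint is used.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeBroadPeak <- function(peaks, path) {
    df <- .peakColumns(peaks)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeBroadPeak
#' @export
writeNarrowPeak <- function(peaks, path) {
    df <- .peakColumns(peaks)
    summit <- if (!is.null(mcols(peaks)$summit)) mcols(peaks)$summit
              else (start(peaks) + end(peaks)) %/% 2L
    df$peak <- summit - start(peaks) # 0-based offset from peak start
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

.peakColumns <- function(peaks) {
    data.frame(chrom = as.character(seqnames(peaks)),
               start = start(peaks) - 1L, end = end(peaks),
               name = if (!is.null(peaks$name)) peaks$name
                      else paste0("peak", seq_along(peaks)),
               score = 0L, strand = ".",
               signalValue = if (!is.null(peaks$signalValue)) peaks$signalValue else 0,
               pValue = -1, qValue = -1)
}

#' Export a scaled track as bedGraph
#' @param track a [ScaledTrack-class].
#' @param path output bedGraph file.
#' @return invisibly, \code{path}.
#' @export
writeBedGraph <- function(track, path) {
    sl <- seqLengths(track)
    bins <- tileGenome(sl, tilewidth = binSize(track),
                       cut.last.tile.in.chrom = TRUE)
    bins <- GenomicRanges::sort(bins)
    mcols(bins)$score <- unlist(lapply(names(trackValues(track)),
                                       function(chr) trackValues(track)[[chr]]),
                                use.names = FALSE)
    export(bins, path, format = "bedGraph")
    invisible(path)
}

#' Write differential peaks as BED6+3 (M, M_norm, p)
#' @param peaks \code{GRanges} with \code{M}, \code{M_norm}, \code{p_value}
#'   and \code{direction} metadata columns.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeDifferentialPeaks <- function(peaks, path) {
    df <- data.frame(chrom = as.character(seqnames(peaks)),
                     start = start(peaks) - 1L, end = end(peaks),
                     name = if (length(peaks)) paste0("dpeak", seq_along(peaks),
                                                      "_", peaks$direction)
                            else character(0),
                     score = 0L, strand = ".",
                     M = if (!is.null(peaks$M)) peaks$M else NA,
                     M_norm = if (!is.null(peaks$M_norm)) peaks$M_norm else NA,
                     p = if (!is.null(peaks$p_value)) peaks$p_value else NA)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a complete synthetic study to disk
#'
#' Materializes a [generateStudy()] fixture as the plain-text formats the
#' pipeline consumes: genome FASTA, gene GFF3, per-library fragment BED6,
#' per-replicate broadPeak calls (plus merged-replicate wt H2Aub1 summits as
#' narrowPeak), DE and responsiveness TSVs, and the ground truth and
#' configuration as JSON.
#'
#' @param fixture a \code{StudyFixture} from [generateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeStudy <- function(fixture, dir) {
    stopifnot(inherits(fixture, "StudyFixture"))
    dir.create(file.path(dir, "fragments"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
    writeXStringSet(fixture$genome, file.path(dir, "genome.fa"))
    writeGenesGff3(fixture$genes, file.path(dir, "genes.gff3"))
    for (nm in names(fixture$libraries))
        writeFragmentBed(fixture$libraries[[nm]],
                         file.path(dir, "fragments", paste0(nm, ".bed")))
    for (nm in names(fixture$peaks))
        writeBroadPeak(fixture$peaks[[nm]],
                       file.path(dir, "peaks", paste0(nm, ".broadPeak")))
    summits <- fixture$h2aubSummits
    summitPeaks <- GRanges(seqnames(summits),
                           IRanges(pmax(1L, start(summits) - 249L), width = 500L))
    mcols(summitPeaks)$summit <- start(summits)
    writeNarrowPeak(summitPeaks,
                    file.path(dir, "peaks", "H2Aub1_wt_summits.narrowPeak"))
    write.table(fixture$deTable, file.path(dir, "de_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = names(fixture$responsiveness),
                           score = unname(fixture$responsiveness)),
                file.path(dir, "responsiveness.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gt <- fixture$groundTruth
    gtJson <- list(
        target_genes = gt$target_genes,
        loss_genes = gt$loss_genes,
        mark_assignment = as.list(gt$mark_assignment),
        motif_positions = .grToBedDf(gt$motif_positions),
        cluster_positions = .grToBedDf(gt$cluster_positions),
        planted_ref6_slope = gt$planted_ref6_slope,
        planted_de = as.list(gt$planted_de))
    jsonlite::write_json(gtJson, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(fixture$config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

.grToBedDf <- function(gr) {
    data.frame(chrom = as.character(seqnames(gr)),
               start = start(gr) - 1L, end = end(gr),
               strand = as.character(strand(gr)))
}
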