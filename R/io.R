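#' Write / read a gene count table
#'
#' Tab-separated with columns `feature`, `length`, then one column per
#' sample; a commented header block records the sample metadata.
#'
#' @param x a [CountExperiment-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCountsTsv <- function(x, path) {
    cd <- colData(x)
    hdr <- paste0("# sample\t", paste(rownames(cd), collapse = "\t"), "\n",
                  "# cell_type\t", paste(cd$cell_type, collapse = "\t"), "\n",
                  "# stage\t", paste(cd$stage, collapse = "\t"), "\n",
                  "# replicate\t", paste(cd$replicate, collapse = "\t"))
    df <- data.frame(feature = rownames(x), length = rowData(x)$length,
                     counts(x), check.names = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountsTsv
#' @param path path to a counts TSV written by [writeCountsTsv()]
#' @export
readCountsTsv <- function(path) {
    hdr <- readLines(path, n = 4L)
    meta <- lapply(strsplit(sub("^# ", "", hdr), "\t"), `[`, -1L)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "#", check.names = FALSE)
    counts <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(counts) <- df$feature
    CountExperiment(counts, lengths = df$length, cellType = meta[[2]],
                    stage = meta[[3]], replicate = as.integer(meta[[4]]))
}

#' Write / read an intron measurement table
#'
#' Columns: `gene`, `intron`, `depth`, `ss5`, `ss3`, `sample`.
#'
#' @param x intron data.frame (see [simulateIntrons()])
#' @param path file path
#' @return `path` invisibly / the data.frame
#' @export
writeIntronTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeIntronTsv
#' @export
readIntronTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE)
}

#' Write / read paired-end fragments as BED6
#'
#' BED6 with 0-based half-open intervals; the score column carries the
#' mapping quality.
#'
#' @param fragments data.frame with `chrom`, `start`, `end`, `mapq`
#' @param path file path
#' @return `path` invisibly / the fragments data.frame
#' @export
writeFragmentsBed <- function(fragments, path) {
    bed <- data.frame(fragments$chrom, fragments$start, fragments$end,
                      name = ".", score = fragments$mapq, strand = ".")
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeFragmentsBed
#' @export
readFragmentsBed <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE)
    data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
               mapq = df[[5]])
}

#' Write a bismark-dialect CpG coverage file
#'
#' Columns: chrom, start, end, percent methylation, count methylated,
#' count unmethylated (tab-separated, no header).
#'
#' @param cpgs CpG record data.frame (`chrom`, `start`, `end`,
#'   `methylated`, `unmethylated`)
#' @param path file path
#' @return `path`, invisibly
#' @seealso [readBismarkCoverage()]
#' @export
writeBismarkCoverage <- function(cpgs, path) {
    cov <- cpgs$methylated + cpgs$unmethylated
    pct <- ifelse(cov > 0, 100 * cpgs$methylated / cov, 0)
    out <- data.frame(cpgs$chrom, cpgs$start, cpgs$end, pct,
                      cpgs$methylated, cpgs$unmethylated)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write / read a labeled mask as a plain text grid
#'
#' One row of space-separated integer labels per mask row.
#'
#' @param mask integer matrix (or [CellGeometry-class])
#' @param path file path
#' @return `path` invisibly / an integer matrix
#' @export
writeMaskGrid <- function(mask, path) {
    if (is(mask, "CellGeometry")) mask <- mask@mask
    utils::write.table(mask, path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeMaskGrid
#' @export
readMaskGrid <- function(path) {
    m <- as.matrix(utils::read.table(path, sep = ""))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
}

#' Write peaks in narrowPeak layout
#'
#' Ten-column ENCODE narrowPeak: the 7th column holds fold enrichment, the
#' 8th the -log10 p score, the 10th the summit offset from the peak start.
#'
#' @param peaks `GRanges` from [callPeaks()]
#' @param path file path
#' @return `path`, invisibly
#' @export
writeNarrowPeak <- function(peaks, path) {
    df <- data.frame(
        as.character(GenomicRanges::seqnames(peaks)),
        GenomicRanges::start(peaks) - 1L, GenomicRanges::end(peaks),
        paste0("peak_", seq_along(peaks)), 0L, ".",
        peaks$foldEnrichment, peaks$score, -1,
        peaks$summit - GenomicRanges::start(peaks))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeNarrowPeak
#' @export
readNarrowPeak <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE)
    GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]),
                           score = df[[8]], foldEnrichment = df[[7]],
                           summit = df[[2]] + 1L + df[[10]])
}

#' Write a cut-site track as bedGraph
#'
#' Emits one line per coverage run (0-based half-open intervals), suitable
#' for genome-browser inspection. Zero-coverage runs are omitted.
#'
#' @param track a [CutSiteTrack-class]
#' @param path file path
#' @param trackName name written in the track header line
#' @return `path`, invisibly
#' @export
writeBedGraph <- function(track, path, trackName = "cutsites") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", trackName), con)
    for (cname in names(track@coverage)) {
        r <- track@coverage[[cname]]
        ends <- cumsum(S4Vectors::runLength(r))
        starts <- c(0, ends[-length(ends)])
        vals <- S4Vectors::runValue(r)
        keep <- vals != 0
        if (!any(keep)) next
        utils::write.table(
            data.frame(cname, starts[keep], ends[keep], vals[keep]),
            con, sep = "\t", quote = FALSE, row.names = FALSE,
            col.names = FALSE)
    }
    invisible(path)
}

#' Extract TSS, exons and gene bodies from a GTF file
#'
#' Thin wrapper over `rtracklayer::import` returning the three `GRanges`
#' that [annotateElements()] consumes.
#'
#' @param path GTF file path
#' @return list with `tss`, `exons`, `genes` (`GRanges`)
#' @export
readGeneModels <- function(path) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
        stop("rtracklayer is required to read GTF files")
    gr <- rtracklayer::import(path)
    genes <- gr[gr$type %in% c("gene", "transcript")]
    exons <- gr[gr$type == "exon"]
    if (!length(genes)) genes <- exons
    tss <- GenomicRanges::resize(genes, width = 1L, fix = "start")
    list(tss = tss, exons = exons, genes = genes)
}
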