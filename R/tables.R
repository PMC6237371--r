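#' Read and write counts and sample-metadata tables
#'
#' Counts TSV: header row of sample ids, first column the region id.
#' Metadata TSV: columns sample_id, immunophenotype, subtype, batch.
#'
#' @param path file path.
#' @return \code{readCountsTsv}: integer matrix (regions x samples);
#'   \code{readSampleMetaTsv}: data.frame.
#' @export
readCountsTsv <- function(path) {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- dt[[1]]
    storage.mode(m) <- "integer"
    m
}

#' @rdname readCountsTsv
#' @param counts integer matrix with region-id rownames.
#' @export
writeCountsTsv <- function(counts, path) {
    dt <- data.table::data.table(region_id = rownames(counts))
    dt <- cbind(dt, data.table::as.data.table(counts))
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' @rdname readCountsTsv
#' @export
readSampleMetaTsv <- function(path) {
    as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
}

#' @rdname readCountsTsv
#' @param meta sample metadata data.frame.
#' @export
writeSampleMetaTsv <- function(meta, path) {
    data.table::fwrite(meta, path, sep = "\t")
    invisible(path)
}

#' Write a full simulation to plain-text files
#'
#' Emits the genome layout (TSV), gene and vlincRNA annotations (BED6),
#' the pooled coverage (bedGraph pair), counts and metadata (TSV), the
#' chromatin-state segmentation (BED4 via the name column) and WGBS CpG
#' counts (TSV), plus the planted truth as JSON. All files round-trip
#' through the package's own readers.
#'
#' @param sim output of [simulateAll()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    paths <- c(genome = p("genome.tsv"), genes = p("genes.bed"),
               vlincs = p("vlincs.bed"), counts = p("counts.tsv"),
               meta = p("meta.tsv"), truth = p("truth.json"))
    writeGenomeLayout(sim$truth$layout, paths["genome"])
    writeBed(sim$truth$genes, paths["genes"])
    writeBed(sim$truth$vlincs, paths["vlincs"])
    writeCountsTsv(SummarizedExperiment::assay(sim$counts, "counts"),
                   paths["counts"])
    writeSampleMetaTsv(sim$meta, paths["meta"])
    if (!is.null(sim$pooled)) {
        paths <- c(paths, cov_plus = p("pooled.plus.bedgraph"),
                   cov_minus = p("pooled.minus.bedgraph"))
        writeBedGraphPair(sim$pooled, paths["cov_plus"], paths["cov_minus"])
    }
    if (!is.null(sim$chromatin)) {
        paths <- c(paths, states = p("states.bed"), meth = p("methylation.tsv"))
        st <- sim$chromatin$states
        mcols(st)$name <- mcols(st)$state
        writeBed(st, paths["states"])
        writeMethylationTsv(sim$chromatin$meth, paths["meth"])
    }
    tr <- sim$truth
    truth_json <- list(
        seed = tr$seed,
        subtypes = tr$subtypes,
        vlincs = data.frame(id = names(tr$vlincs),
                            chrom = as.character(seqnames(tr$vlincs)),
                            start0 = start(tr$vlincs) - 1L,
                            end0 = end(tr$vlincs),
                            strand = as.character(strand(tr$vlincs)),
                            base_level = mcols(tr$vlincs)$base_level,
                            specific_subtype = mcols(tr$vlincs)$specific_subtype),
        expression = as.data.frame(tr$expression),
        active_promoter = if (!is.null(sim$chromatin))
            as.list(sim$chromatin$active_promoter) else NULL)
    jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(paths)
}
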