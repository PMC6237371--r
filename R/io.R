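#' Construct a genome layout
#'
#' @param chrom character vector of unique chromosome names.
#' @param length numeric vector of chromosome lengths in bp.
#' @param autosome logical vector of autosome flags (explicit, one per
#'   chromosome; defaults to all TRUE).
#' @return a [GenomeLayout-class].
#' @examples
#' GenomeLayout(c("chr1", "chrX"), c(1e6, 5e5), c(TRUE, FALSE))
#' @export
GenomeLayout <- function(chrom, length, autosome = rep(TRUE, base::length(chrom))) {
    new("GenomeLayout", chrom = as.character(chrom), length = as.numeric(length),
        autosome = as.logical(autosome))
}

## Seqinfo for GRanges built against a layout.
.seqinfo <- function(layout) {
    Seqinfo(seqnames = layout@chrom, seqlengths = as.integer(layout@length))
}

## Empty GRanges carrying the layout's seqinfo.
.emptyGR <- function(layout) GRanges(seqinfo = .seqinfo(layout))

## Convert 0-based half-open (chrom, start, end) to a GRanges on the layout.
## `where` names the source (file + line numbers) for error messages.
.gr0 <- function(layout, chrom, start0, end0, strand = "*", where = NULL) {
    bad <- which(!(start0 >= 0 & start0 < end0))
    if (length(bad))
        stop(sprintf("interval with start >= end or negative start%s",
            if (is.null(where)) "" else sprintf(" at %s line %d", where, bad[1])),
            call. = FALSE)
    idx <- match(chrom, layout@chrom)
    if (anyNA(idx))
        stop(sprintf("unknown chromosome '%s'%s", chrom[which(is.na(idx))[1]],
            if (is.null(where)) "" else sprintf(" in %s", where)), call. = FALSE)
    over <- which(end0 > layout@length[idx])
    if (length(over))
        stop(sprintf("interval beyond chromosome end%s",
            if (is.null(where)) "" else sprintf(" at %s line %d", where, over[1])),
            call. = FALSE)
    GRanges(chrom, IRanges(start0 + 1, end0), strand = strand,
            seqinfo = .seqinfo(layout))
}

#' Read a genome layout from TSV
#'
#' Expects 2 or 3 tab-separated columns without header: name, length, and an
#' optional autosome flag (0/1). With two columns every chromosome is flagged
#' autosomal.
#'
#' @param path file path.
#' @return a [GenomeLayout-class].
#' @export
readGenomeLayout <- function(path) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 2) stop("genome layout needs at least name and length columns")
    auto <- if (ncol(dt) >= 3) as.logical(dt[[3]]) else rep(TRUE, nrow(dt))
    GenomeLayout(dt[[1]], dt[[2]], auto)
}

#' Write a genome layout as TSV
#'
#' @param layout a [GenomeLayout-class].
#' @param path file path.
#' @export
writeGenomeLayout <- function(layout, path) {
    data.table::fwrite(
        data.table::data.table(layout@chrom, as.integer(layout@length),
                               as.integer(layout@autosome)),
        path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read intervals from a BED3/BED6 file
#'
#' Tab-separated, no header. BED coordinates (0-based half-open) become the
#' 1-based closed convention of \code{GRanges}; strand "." maps to "*"
#' (unstranded). Malformed lines raise an error naming the line. Records on
#' chromosomes absent from the layout are skipped with a warning by default.
#'
#' @param path file path.
#' @param layout a [GenomeLayout-class]; intervals are validated against it.
#' @param strict if TRUE, unknown chromosomes are an error instead of a
#'   skip-with-warning.
#' @return a \code{GRanges} (with \code{name}/\code{score} metadata columns
#'   when the file has 4+ columns).
#' @export
readBed <- function(path, layout, strict = FALSE) {
    if (file.exists(path) && file.size(path) == 0) return(.emptyGR(layout))
    dt <- tryCatch(
        data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1)),
        error = function(e) stop(sprintf("malformed BED file '%s': %s",
                                         path, conditionMessage(e)), call. = FALSE))
    if (nrow(dt) == 0) return(.emptyGR(layout))
    if (ncol(dt) < 3) stop(sprintf("BED file '%s' needs at least 3 columns", path))
    start0 <- suppressWarnings(as.numeric(dt[[2]]))
    end0 <- suppressWarnings(as.numeric(dt[[3]]))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad))
        stop(sprintf("malformed BED line %d in '%s'", bad[1], path), call. = FALSE)
    keep <- dt[[1]] %in% layout@chrom
    if (!all(keep)) {
        if (strict)
            stop(sprintf("unknown chromosome '%s' at BED line %d in '%s'",
                         dt[[1]][!keep][1], which(!keep)[1], path), call. = FALSE)
        warning(sprintf("skipping %d BED record(s) on chromosomes absent from layout",
                        sum(!keep)))
        dt <- dt[keep]; start0 <- start0[keep]; end0 <- end0[keep]
        if (nrow(dt) == 0) return(.emptyGR(layout))
    }
    strand <- if (ncol(dt) >= 6) ifelse(dt[[6]] %in% c("+", "-"), dt[[6]], "*") else "*"
    gr <- .gr0(layout, dt[[1]], start0, end0, strand, where = path)
    if (ncol(dt) >= 4) mcols(gr)$name <- as.character(dt[[4]])
    if (ncol(dt) >= 5) mcols(gr)$score <- suppressWarnings(as.numeric(dt[[5]]))
    gr
}

#' Write intervals as BED6
#'
#' @param gr a \code{GRanges}; \code{name}/\code{score} metadata columns are
#'   used when present (name falls back to \code{names(gr)}, score to 0).
#' @param path file path.
#' @export
writeBed <- function(gr, path) {
    nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name
          else if (!is.null(names(gr))) names(gr) else rep(".", length(gr))
    sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, length(gr))
    st <- as.character(strand(gr)); st[st == "*"] <- "."
    data.table::fwrite(
        data.table::data.table(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                               nm, sc, st),
        path, sep = "\t", col.names = FALSE)
    invisible(path)
}

## Parse one bedGraph file into per-chromosome integer Rles.
.readBedGraphStrand <- function(path, layout, strict = FALSE) {
    zero <- RleList(lapply(setNames(as.integer(layout@length), layout@chrom),
                           function(n) Rle(0L, n)), compress = FALSE)
    if (is.null(path) || (file.exists(path) && file.size(path) == 0))
        return(zero)
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1))
    if (nrow(dt) == 0) return(zero)
    if (ncol(dt) < 4) stop(sprintf("bedGraph '%s' needs 4 columns", path))
    depth <- suppressWarnings(as.numeric(dt[[4]]))
    if (anyNA(depth) || any(depth != floor(depth)))
        stop(sprintf("non-integer depth at line %d in '%s'",
                     which(is.na(depth) | depth != floor(depth))[1], path), call. = FALSE)
    if (any(depth < 0))
        stop(sprintf("negative depth at line %d in '%s'", which(depth < 0)[1], path),
             call. = FALSE)
    keep <- dt[[1]] %in% layout@chrom
    if (!all(keep)) {
        if (strict)
            stop(sprintf("unknown chromosome '%s' at line %d in '%s'",
                         dt[[1]][!keep][1], which(!keep)[1], path), call. = FALSE)
        warning(sprintf("skipping %d bedGraph record(s) on unknown chromosomes",
                        sum(!keep)))
        dt <- dt[keep]; depth <- depth[keep]
        if (nrow(dt) == 0) return(zero)
    }
    gr <- .gr0(layout, dt[[1]], dt[[2]], dt[[3]], where = path)
    ## overlapping records on one strand are ambiguous - refuse them
    if (sum(width(reduce(gr, min.gapwidth = 0L))) < sum(as.numeric(width(gr))))
        stop(sprintf("overlapping bedGraph records in '%s'", path), call. = FALSE)
    rl <- coverage(gr, weight = as.integer(depth))
    rl[layout@chrom]
}

#' Read a strand-specific coverage pair from bedGraph files
#'
#' One bedGraph per strand (tab-separated, no header, 0-based half-open,
#' integer depths). Uncovered bases have depth 0 implicitly. Negative depths
#' and overlapping records are errors.
#'
#' @param path_plus,path_minus file paths (either may be NULL for an
#'   all-zero strand).
#' @param layout a [GenomeLayout-class].
#' @param strict error (rather than warn and skip) on unknown chromosomes.
#' @return a [CoverageTrack-class].
#' @export
readBedGraphPair <- function(path_plus, path_minus, layout, strict = FALSE) {
    new("CoverageTrack", layout = layout,
        plus = .readBedGraphStrand(path_plus, layout, strict),
        minus = .readBedGraphStrand(path_minus, layout, strict))
}

#' Write a coverage track as a pair of bedGraph files
#'
#' Only non-zero runs are written, as 0-based half-open records.
#'
#' @param track a [CoverageTrack-class].
#' @param path_plus,path_minus output file paths.
#' @export
writeBedGraphPair <- function(track, path_plus, path_minus) {
    wr <- function(rl, path) {
        recs <- lapply(names(rl), function(chr) {
            r <- rl[[chr]]
            ir <- as(r >= 1L, "IRanges")
            if (length(ir) == 0) return(NULL)
            ## split covered ranges into constant-depth runs
            v <- Views(r, ir)
            out <- lapply(seq_along(ir), function(i) {
                seg <- as(v[[i]], "Rle")
                ends <- cumsum(runLength(seg))
                data.table::data.table(
                    chr, start(ir)[i] - 1L + c(0L, head(ends, -1L)),
                    start(ir)[i] - 1L + ends, runValue(seg))
            })
            data.table::rbindlist(out)
        })
        dt <- data.table::rbindlist(recs[!vapply(recs, is.null, NA)])
        if (nrow(dt) == 0) dt <- data.table::data.table(character(), integer(),
                                                        integer(), integer())
        data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    }
    wr(track@plus, path_plus)
    wr(track@minus, path_minus)
    invisible(c(path_plus, path_minus))
}

#' Read a chromatin-state segmentation (dense BED)
#'
#' Four tab-separated columns: chrom, start, end, state label. Returns an
#' unstranded \code{GRanges} with a \code{state} metadata column.
#'
#' @inheritParams readBed
#' @export
readStateBed <- function(path, layout, strict = FALSE) {
    gr <- readBed(path, layout, strict)
    if (length(gr) && is.null(mcols(gr)$name))
        stop(sprintf("state segmentation '%s' needs a 4th (state) column", path))
    mcols(gr)$state <- mcols(gr)$name
    mcols(gr)$name <- NULL
    gr
}
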