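#' Construct a methylation track from per-CpG counts
#'
#' @param layout a [GenomeLayout-class].
#' @param chrom chromosome names.
#' @param pos0 0-based CpG positions.
#' @param meth,unmeth methylated / unmethylated read counts.
#' @return a [MethylationTrack-class].
#' @export
MethylationTrack <- function(layout, chrom = character(), pos0 = integer(),
                             meth = integer(), unmeth = integer()) {
    gr <- if (length(chrom))
        .gr0(layout, chrom, pos0, pos0 + 1) else .emptyGR(layout)
    mcols(gr)$meth <- as.integer(meth)
    mcols(gr)$unmeth <- as.integer(unmeth)
    new("MethylationTrack", layout = layout, sites = sort(gr))
}

#' Read WGBS CpG counts from TSV
#'
#' Four tab-separated columns without header: chrom, 0-based position,
#' methylated count, unmethylated count.
#'
#' @param path file path.
#' @param layout a [GenomeLayout-class].
#' @param strict error on unknown chromosomes instead of skipping.
#' @return a [MethylationTrack-class].
#' @export
readMethylationTsv <- function(path, layout, strict = FALSE) {
    if (file.exists(path) && file.size(path) == 0)
        return(MethylationTrack(layout))
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1))
    if (nrow(dt) == 0) return(MethylationTrack(layout))
    keep <- dt[[1]] %in% layout@chrom
    if (!all(keep)) {
        if (strict) stop(sprintf("unknown chromosome '%s' in '%s'",
                                 dt[[1]][!keep][1], path), call. = FALSE)
        warning(sprintf("skipping %d CpG record(s) on unknown chromosomes",
                        sum(!keep)))
        dt <- dt[keep]
    }
    MethylationTrack(layout, dt[[1]], dt[[2]], dt[[3]], dt[[4]])
}

#' Write a methylation track as TSV
#'
#' @param track a [MethylationTrack-class].
#' @param path file path.
#' @export
writeMethylationTsv <- function(track, path) {
    s <- track@sites
    data.table::fwrite(
        data.table::data.table(as.character(seqnames(s)), start(s) - 1L,
                               mcols(s)$meth, mcols(s)$unmeth),
        path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Merge WGBS replicates by summing counts
#'
#' Per CpG, methylated and unmethylated counts are summed across tracks; a
#' CpG is present in the result if present in any input (union).
#'
#' @param tracks list of [MethylationTrack-class] on one layout.
#' @return a [MethylationTrack-class].
#' @export
mergeWgbs <- function(tracks) {
    stopifnot(length(tracks) >= 1)
    lay <- tracks[[1]]@layout
    dt <- data.table::rbindlist(lapply(tracks, function(t) {
        if (!identical(t@layout@chrom, lay@chrom))
            stop("all tracks must share one genome layout")
        s <- t@sites
        data.table::data.table(chrom = as.character(seqnames(s)),
                               pos0 = start(s) - 1L,
                               meth = mcols(s)$meth, unmeth = mcols(s)$unmeth)
    }))
    if (nrow(dt) == 0) return(MethylationTrack(lay))
    agg <- dt[, list(meth = sum(meth), unmeth = sum(unmeth)),
              by = c("chrom", "pos0")]
    MethylationTrack(lay, agg$chrom, agg$pos0, agg$meth, agg$unmeth)
}

## Mean beta of covered CpGs per query range; one findOverlaps pass.
## Returns NA where a range contains no covered CpG.
.meanBetaPerRange <- function(track, bins, weighted = FALSE) {
    s <- track@sites
    tot <- mcols(s)$meth + mcols(s)$unmeth
    covered <- which(tot > 0)
    out <- rep(NA_real_, length(bins))
    ncpg <- integer(length(bins))
    if (length(covered) == 0 || length(bins) == 0)
        return(list(mean = out, n = ncpg))
    hits <- findOverlaps(s[covered], bins, ignore.strand = TRUE)
    if (length(hits) == 0) return(list(mean = out, n = ncpg))
    ci <- covered[queryHits(hits)]
    beta <- mcols(s)$meth[ci] / tot[ci]
    wgt <- if (weighted) tot[ci] else rep(1, length(ci))
    bi <- subjectHits(hits)
    num <- rowsum(beta * wgt, bi)
    den <- rowsum(wgt, bi)
    cnt <- rowsum(rep(1L, length(bi)), bi)
    idx <- as.integer(rownames(num))
    out[idx] <- num[, 1] / den[, 1]
    ncpg[idx] <- cnt[, 1]
    list(mean = out, n = ncpg)
}

## 0-based bin boundaries splitting [0, L) into k equal parts, fractional
## boundaries rounded half-up.
.equalBins0 <- function(L, k) floor((0:k) * L / k + 0.5)

#' Binned methylation metaprofile over regions and flanks
#'
#' Each region contributes 3 x \code{bins_per_part} bins: the upstream
#' flank, the region body and the downstream flank, each split into
#' \code{bins_per_part} equal-size bins (fractional body boundaries rounded
#' half-up). The per-bin value is the mean beta of covered CpGs in the bin;
#' bins containing no covered CpG are missing, never 0. Rows are oriented
#' 5' to 3' by region strand (minus-strand rows reversed) unless
#' \code{orient = FALSE}. The across-region mean curve ignores missing
#' bins.
#'
#' @param track a [MethylationTrack-class].
#' @param regions non-empty stranded \code{GRanges} (e.g. refined
#'   promoters).
#' @param flank flank size in bp (default 10000).
#' @param bins_per_part bins per segment (default 10, i.e. each data point
#'   is 10% of region or flank size).
#' @param weighted weight CpG betas by coverage instead of the default
#'   unweighted mean.
#' @param orient orient rows 5' to 3' (default) rather than left-to-right
#'   genomic.
#' @return a list: \code{matrix} (regions x 3*bins_per_part beta means,
#'   NA = no covered CpG), \code{occupancy} (covered-CpG counts per bin),
#'   \code{curve} (per-bin means over regions, NA bins ignored).
#' @export
binnedProfile <- function(track, regions, flank = 10000, bins_per_part = 10,
                          weighted = FALSE, orient = TRUE) {
    if (length(regions) == 0) stop("regions must be non-empty")
    if (any(width(regions) < bins_per_part))
        stop("region shorter than bins_per_part bases")
    k <- bins_per_part
    chrlen <- chromLengths(track@layout)
    allbins <- vector("list", length(regions))
    for (i in seq_along(regions)) {
        chr <- as.character(seqnames(regions)[i])
        s0 <- start(regions)[i] - 1L
        e0 <- end(regions)[i]
        b_up <- s0 - flank + .equalBins0(flank, k)
        b_body <- s0 + .equalBins0(e0 - s0, k)
        b_dn <- e0 + .equalBins0(flank, k)
        lo <- c(head(b_up, -1), head(b_body, -1), head(b_dn, -1))
        hi <- c(tail(b_up, -1), tail(b_body, -1), tail(b_dn, -1))
        ## clip to the chromosome; empty or off-genome bins stay NA
        lo_c <- pmax(lo, 0); hi_c <- pmin(hi, chrlen[chr])
        valid <- hi_c > lo_c
        gr <- GRanges(chr, IRanges(lo_c[valid] + 1, hi_c[valid]),
                      seqinfo = .seqinfo(track@layout))
        mcols(gr)$slot <- which(valid)
        allbins[[i]] <- gr
    }
    bins <- do.call(c, allbins)
    mb <- .meanBetaPerRange(track, bins, weighted)
    nb <- 3L * k
    mat <- matrix(NA_real_, length(regions), nb)
    occ <- matrix(0L, length(regions), nb)
    reg_of <- rep(seq_along(regions), vapply(allbins, length, 0L))
    mat[cbind(reg_of, mcols(bins)$slot)] <- mb$mean
    occ[cbind(reg_of, mcols(bins)$slot)] <- mb$n
    if (orient) {
        rev_idx <- which(as.character(strand(regions)) == "-")
        if (length(rev_idx)) {
            mat[rev_idx, ] <- mat[rev_idx, nb:1, drop = FALSE]
            occ[rev_idx, ] <- occ[rev_idx, nb:1, drop = FALSE]
        }
    }
    ids <- names(regions)
    if (!is.null(ids)) { rownames(mat) <- ids; rownames(occ) <- ids }
    list(matrix = mat, occupancy = occ,
         curve = colMeans(mat, na.rm = TRUE))
}

#' Mean promoter methylation
#'
#' Unweighted (or coverage-weighted) mean beta of covered CpGs per region;
#' missing when a region has no covered CpG.
#'
#' @param track a [MethylationTrack-class].
#' @param regions \code{GRanges}.
#' @param weighted weight by CpG coverage.
#' @return numeric vector, one mean beta per region (NA = no covered CpG),
#'   named when \code{regions} is named.
#' @export
promoterMeanMeth <- function(track, regions, weighted = FALSE) {
    mb <- .meanBetaPerRange(track, regions, weighted)
    out <- mb$mean
    if (!is.null(names(regions))) names(out) <- names(regions)
    out
}
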