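#' Merge intervals closer than a gap threshold
#'
#' Same-chromosome, same-strand intervals whose gap is strictly less than
#' \code{max_gap} bp are united (adjacent and overlapping intervals always
#' merge). The result is disjoint per chromosome and strand with all
#' remaining gaps >= \code{max_gap}; the operation is idempotent.
#'
#' @param gr a \code{GRanges}.
#' @param max_gap gap threshold in bp (strict "less than").
#' @param ignore_strand merge across strands.
#' @return a sorted, reduced \code{GRanges}.
#' @examples
#' lay <- GenomeLayout("chr1", 1e6)
#' gr <- GRanges("chr1", IRanges(c(1, 451), c(100, 500)), strand = "+")
#' mergeWithin(gr, 500)   # gap 350 < 500 -> one interval
#' @export
mergeWithin <- function(gr, max_gap, ignore_strand = FALSE) {
    stopifnot(max_gap >= 0)
    ## reduce() leaves ranges separated by >= min.gapwidth unmerged, which is
    ## exactly the strict "< max_gap are merged" rule
    sort(reduce(gr, min.gapwidth = max_gap, ignore.strand = ignore_strand))
}

#' Remove the bases of one interval set from another
#'
#' Every base of the result lies in \code{a} and not in \code{b} (on the
#' same strand when \code{strand_aware}). Base counts are conserved:
#' |result| = |a| - |a intersect b|.
#'
#' @param a,b \code{GRanges}.
#' @param strand_aware when TRUE, only same-strand bases of \code{b} are
#'   removed; unstranded ("*") intervals in \code{b} hit both strands.
#' @return a \code{GRanges}.
#' @export
subtractIntervals <- function(a, b, strand_aware = TRUE) {
    if (length(b) == 0) return(sort(reduce(a, min.gapwidth = 0L,
                                           ignore.strand = !strand_aware)))
    if (!strand_aware) {
        a2 <- a; strand(a2) <- "*"
        b2 <- b; strand(b2) <- "*"
        return(sort(GenomicRanges::setdiff(a2, b2, ignore.strand = TRUE)))
    }
    ## unstranded b records apply to both strands
    bstar <- b[strand(b) == "*"]
    bboth <- b
    if (length(bstar)) {
        bp <- bstar; strand(bp) <- "+"
        bm <- bstar; strand(bm) <- "-"
        bboth <- c(b[strand(b) != "*"], bp, bm)
    }
    sort(GenomicRanges::setdiff(a, bboth, ignore.strand = FALSE))
}

#' Keep intervals at least a minimum distance from another set
#'
#' An interval of \code{a} is kept iff no interval of \code{b} on the same
#' chromosome lies closer than \code{min_dist} bp, ignoring strand; overlap
#' counts as distance 0 ("at least min_dist away" is >= on the gap).
#'
#' @param a,b \code{GRanges}.
#' @param min_dist minimum gap in bp.
#' @return the surviving subset of \code{a}.
#' @export
distanceFilter <- function(a, b, min_dist) {
    if (length(a) == 0 || length(b) == 0) return(a)
    hits <- GenomicRanges::distanceToNearest(a, b, ignore.strand = TRUE)
    near <- queryHits(hits)[mcols(hits)$distance < min_dist]
    if (length(near) == 0) a else a[-unique(near)]
}

## Draw uniform placements for n intervals of the given lengths on a layout:
## chromosome with probability proportional to length, start uniform in
## [0, chrom_len - len]. Returns 0-based starts and chromosome indices.
.drawPlacements <- function(lens, layout) {
    ok <- outer(layout@length, lens, ">=")     # chrom x interval feasibility
    p <- layout@length
    idx <- vapply(seq_along(lens), function(i) {
        feas <- which(ok[, i])
        if (length(feas) == 0)
            stop("interval longer than every chromosome", call. = FALSE)
        if (length(feas) == 1) feas else sample(feas, 1, prob = p[feas])
    }, 0L)
    start0 <- floor(runif(length(lens)) * (layout@length[idx] - lens + 1))
    list(chrom = idx, start0 = start0)
}

## Vectorised multi-replicate shuffle; returns GRanges with mcols rep
## (replicate index) and src (input interval index). Strand preserved.
.shuffleReps <- function(gr, layout, n_reps, exclude = NULL, max_tries = 1000L) {
    n <- length(gr)
    if (n_reps == 0 || n == 0)
        return(GRanges(seqinfo = .seqinfo(layout)))
    lens <- rep(width(gr), n_reps)
    src <- rep(seq_len(n), n_reps)
    repv <- rep(seq_len(n_reps), each = n)
    pl <- .drawPlacements(lens, layout)
    out <- GRanges(layout@chrom[pl$chrom], IRanges(pl$start0 + 1, width = lens),
                   strand = rep(strand(gr), n_reps), seqinfo = .seqinfo(layout))
    if (!is.null(exclude) && length(exclude)) {
        tries <- 0L
        bad <- which(countOverlaps(out, exclude, ignore.strand = TRUE) > 0)
        while (length(bad)) {
            tries <- tries + 1L
            if (tries > max_tries)
                stop(sprintf("%d interval(s) unplaceable outside excluded regions after %d tries",
                             length(bad), max_tries), call. = FALSE)
            pl <- .drawPlacements(lens[bad], layout)
            repl <- GRanges(layout@chrom[pl$chrom],
                            IRanges(pl$start0 + 1, width = lens[bad]),
                            strand = strand(out)[bad], seqinfo = .seqinfo(layout))
            out[bad] <- repl
            bad <- bad[countOverlaps(repl, exclude, ignore.strand = TRUE) > 0]
        }
    }
    mcols(out)$rep <- repv
    mcols(out)$src <- src
    out
}

#' Randomly re-place intervals on the genome (shuffleBed-style)
#'
#' Each input interval is re-placed uniformly at random in every replicate:
#' the chromosome is chosen with probability proportional to its length
#' (among chromosomes long enough), the start uniformly among valid
#' positions. Lengths and strands are preserved exactly. Placements
#' overlapping \code{exclude} are rejected and redrawn (up to
#' \code{max_tries} rounds). Deterministic given \code{seed}.
#'
#' @param gr intervals to shuffle.
#' @param layout a [GenomeLayout-class].
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param exclude optional \code{GRanges} placements must avoid.
#' @param same_chrom keep each interval on its original chromosome.
#' @param max_tries rejection-sampling cap per round.
#' @return a list of \code{n_reps} \code{GRanges}.
#' @export
shuffleIntervals <- function(gr, layout, n_reps, seed, exclude = NULL,
                             same_chrom = FALSE, max_tries = 1000L) {
    set.seed(seed)
    if (n_reps == 0) return(list())
    if (same_chrom) {
        reps <- lapply(seq_len(n_reps), function(i) {
            idx <- match(as.character(seqnames(gr)), layout@chrom)
            lens <- width(gr)
            if (any(lens > layout@length[idx]))
                stop("interval longer than its own chromosome", call. = FALSE)
            start0 <- floor(runif(length(gr)) * (layout@length[idx] - lens + 1))
            out <- GRanges(layout@chrom[idx], IRanges(start0 + 1, width = lens),
                           strand = strand(gr), seqinfo = .seqinfo(layout))
            if (!is.null(exclude) && length(exclude)) {
                tries <- 0L
                bad <- which(countOverlaps(out, exclude, ignore.strand = TRUE) > 0)
                while (length(bad)) {
                    tries <- tries + 1L
                    if (tries > max_tries)
                        stop("unplaceable interval under exclusion", call. = FALSE)
                    s0 <- floor(runif(length(bad)) *
                                (layout@length[idx[bad]] - lens[bad] + 1))
                    out[bad] <- GRanges(layout@chrom[idx[bad]],
                                        IRanges(s0 + 1, width = lens[bad]),
                                        strand = strand(out)[bad],
                                        seqinfo = .seqinfo(layout))
                    bad <- bad[countOverlaps(out[bad], exclude,
                                             ignore.strand = TRUE) > 0]
                }
            }
            out
        })
        return(reps)
    }
    all <- .shuffleReps(gr, layout, n_reps, exclude, max_tries)
    lapply(seq_len(n_reps), function(i) {
        x <- all[mcols(all)$rep == i]
        mcols(x) <- NULL
        x
    })
}
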